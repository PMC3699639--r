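test_that("parameter sets load completely and derived quantities are right", {
  p <- pm3()
  expect_s3_class(p, "nddo_params")
  # hydrogen carries only an s function: no multipole separations
  expect_identical(p$H$dd, 0)
  expect_identical(p$H$qq, 0)
  # heavy-atom separations from the Slater exponents (independent recompute)
  zs <- p$C$zs; zp <- p$C$zp; n <- 2
  dd_ref <- (2 * n + 1) / sqrt(3) * (4 * zs * zp)^(n + 0.5) / (zs + zp)^(2 * n + 2)
  expect_equal(p$C$dd, dd_ref, tolerance = 1e-12)
  expect_gt(p$C$dd, 0)
  expect_gt(p$C$qq, 0)
  # Klopman-Ohno terms reproduce the one-center limits they are fitted to
  ev <- 27.21
  r0 <- p$O$rho0
  expect_equal(1 / (2 * r0), p$O$gss / ev, tolerance = 1e-10)
  r1 <- p$N$rho1
  expect_equal(0.25 * (1 / r1 - 1 / sqrt(p$N$dd^2 + r1^2)),
               p$N$hsp / ev, tolerance = 1e-10)
  # atomic reference energies match the canonical tabulations
  expect_equal(p$H$eisol, -13.073321, tolerance = 1e-6)
  expect_equal(p$C$eisol, -111.229917, tolerance = 1e-5)
  expect_equal(p$N$eisol, -157.6137755, tolerance = 1e-5)
  expect_equal(p$O$eisol, -289.3422065, tolerance = 1e-5)
})

test_that("all three methods load as distinct complete sets", {
  for (m in c("MNDO", "AM1", "PM3")) {
    p <- load_parameters(m, c("H", "C", "N", "O"))
    for (el in c("H", "C", "N", "O")) {
      expect_true(is.finite(p[[el]]$uss))
      expect_gt(p[[el]]$zs, 0)
      expect_true(is.finite(p[[el]]$eisol))
    }
  }
  expect_false(isTRUE(all.equal(load_parameters("AM1", "C")$C$uss,
                                load_parameters("PM3", "C")$C$uss)))
  # MNDO has no Gaussian core-repulsion corrections
  expect_identical(nrow(load_parameters("MNDO", "C")$C$gauss), 0L)
})

test_that("unsupported elements and methods are rejected explicitly", {
  expect_error(load_parameters("PM3", c("C", "Si")), "unsupported element")
  expect_error(load_parameters("PM7", "C"))
})
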