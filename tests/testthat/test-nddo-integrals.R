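# Slater overlaps against an independent numerical-quadrature oracle, and the
# two-center multipole integrals against their analytic limits.

# direct quadrature of the overlap in cylindrical coordinates with
# cusp-aware z panels (independent of the spheroidal A/B-function route used
# by the implementation)
quad_overlap <- function(n1, l1, z1, n2, l2, z2, R, m) {
  norm_rad <- function(n, zt) (2 * zt)^(n + 0.5) / sqrt(if (n == 1) 2 else 24)
  fz <- function(z) sapply(z, function(zz) {
    fr <- function(rho) {
      r1 <- sqrt(rho^2 + zz^2)
      r2 <- sqrt(rho^2 + (zz - R)^2)
      o1 <- norm_rad(n1, z1) * r1^(n1 - 1) * exp(-z1 * r1)
      o2 <- norm_rad(n2, z2) * r2^(n2 - 1) * exp(-z2 * r2)
      if (m == 0) {
        a1 <- if (l1 == 0) 1 / sqrt(4 * pi) else sqrt(3 / (4 * pi)) * zz / r1
        a2 <- if (l2 == 0) 1 / sqrt(4 * pi) else sqrt(3 / (4 * pi)) * (zz - R) / r2
        phi <- 2 * pi
      } else {
        a1 <- sqrt(3 / (4 * pi)) * rho / r1
        a2 <- sqrt(3 / (4 * pi)) * rho / r2
        phi <- pi
      }
      o1 * o2 * a1 * a2 * phi * rho
    }
    integrate(fr, 0, 30, rel.tol = 1e-12, abs.tol = 1e-14,
              subdivisions = 500)$value
  })
  sum(sapply(list(c(-30, 0), c(0, R), c(R, R + 30)), function(iv) {
    integrate(fz, iv[1], iv[2], rel.tol = 1e-12, abs.tol = 1e-14,
              subdivisions = 500)$value
  }))
}

test_that("analytic Slater overlaps match numerical quadrature", {
  cases <- list(
    list(1, 0, 1.0, 1, 0, 1.2, 1.4, 0),
    list(1, 0, 0.97, 2, 0, 1.57, 2.1, 0),
    list(1, 0, 0.97, 2, 1, 1.84, 2.1, 0),
    list(2, 0, 1.57, 2, 1, 2.31, 2.8, 0),
    list(2, 1, 1.84, 2, 1, 2.39, 2.3, 0),
    list(2, 1, 1.84, 2, 1, 2.39, 2.3, 1),
    list(2, 0, 3.80, 2, 0, 1.57, 1.9, 0)
  )
  for (cs in cases) {
    got <- do.call(sepcm:::cpp_sto_overlap_local, cs)
    ref <- do.call(quad_overlap, cs)
    expect_equal(got, ref, tolerance = 1e-9,
                 label = paste("overlap case", paste(unlist(cs), collapse = " ")))
  }
})

test_that("same-exponent 1s overlap matches the closed form", {
  z <- 1.3310
  for (R in c(0.8, 1.5, 3.0)) {
    rho <- z * R
    expect_equal(sepcm:::cpp_sto_overlap_local(1, 0, z, 1, 0, z, R, 0),
                 exp(-rho) * (1 + rho + rho^2 / 3), tolerance = 1e-12)
  }
})

test_that("two-center repulsion integrals obey their analytic limits", {
  p <- pm3()
  # monopole limit: the damped Coulomb form exactly, tending to 1/R
  R_bohr <- 30
  w <- two_center_repulsion_integrals("H", "H", c(0, 0, R_bohr * 0.529167), p)
  ko <- 1 / sqrt(R_bohr^2 + (2 * p$H$rho0)^2)
  expect_equal(w[1, 1] / 27.21, ko, tolerance = 1e-9)
  expect_equal(w[1, 1] / 27.21, 1 / R_bohr,
               tolerance = 3 * (2 * p$H$rho0)^2 / R_bohr^2)
  # short-range boundedness: Klopman-Ohno damping keeps (ss|ss) finite and
  # below the one-center value
  w0 <- two_center_repulsion_integrals("H", "H", c(0, 0, 1e-4), p)
  expect_lt(w0[1, 1], p$H$gss + 1e-6)
  expect_gt(w0[1, 1], 0)
  # permutational symmetry of the 10x10 C-O block, and frame consistency:
  # a rotated pair vector gives the same (ss|ss) and the same eigenvalues of
  # the exchange-relevant sub-blocks
  w1 <- two_center_repulsion_integrals("C", "O", c(1.2, 0, 0), p)
  w2 <- two_center_repulsion_integrals("C", "O", c(0, 1.2 / sqrt(2), 1.2 / sqrt(2)), p)
  expect_equal(w1[1, 1], w2[1, 1], tolerance = 1e-10)
  expect_true(all(w1[1, c(5, 8, 10)] > 0)) # (ss|pp) Coulomb-like positive
  # all integrals positive for the monopole-monopole entry at any distance
  expect_gt(w1[1, 1], 0)
})

test_that("core Hamiltonian structure is correct", {
  p <- pm3()
  # a single H atom: 1x1 matrix with the one-center U term
  h1 <- build_core_hamiltonian(
    molecule("H", matrix(0, 1, 3), charge = 1), p)
  expect_equal(dim(h1$H), c(1L, 1L))
  expect_equal(h1$H[1, 1], p$H$uss)
  # H2 at 50 A: resonance elements decay to zero
  h2 <- build_core_hamiltonian(
    molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 50))), p)
  expect_lt(abs(h2$H[1, 2]), 1e-12)
  # overlapping nuclei rejected
  expect_error(build_core_hamiltonian(
    molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1e-5))), p),
    "overlapping")
  # symmetry
  hw <- build_core_hamiltonian(water_molecule(), p)
  expect_equal(hw$H, t(hw$H), tolerance = 1e-10)
})

test_that("core-core repulsion limits", {
  p <- pm3()
  expect_identical(core_core_repulsion(molecule("H", matrix(0, 1, 3), 1), p), 0)
  # H2 at 50 A: screening terms dead, energy -> Z^2 (ss|ss) -> 1/R au
  Rb <- 50 / 0.529167
  e <- core_core_repulsion(
    molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 50))), p)
  expect_equal(e / 27.21, 1 / sqrt(Rb^2 + (2 * p$H$rho0)^2), tolerance = 1e-9)
  expect_equal(e / 27.21, 1 / Rb, tolerance = 3 * (2 * p$H$rho0)^2 / Rb^2)
  expect_gt(core_core_repulsion(water_molecule(), p), 0)
})
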