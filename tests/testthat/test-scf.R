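# SCF correctness: published PM3 heats of formation at optimized geometries,
# conservation laws, invariances and the DIIS accelerator.

test_that("optimized PM3 heats of formation reproduce the published values", {
  p <- pm3()
  a <- 1.09 / sqrt(3)
  cases <- list(
    H2 = list(mol = molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.75))),
              ref = -13.4),
    CH4 = list(mol = molecule(c("C", "H", "H", "H", "H"),
                              rbind(c(0, 0, 0), c(a, a, a), c(a, -a, -a),
                                    c(-a, a, -a), c(-a, -a, a))),
               ref = -13.0),
    NH3 = list(mol = molecule(c("N", "H", "H", "H"),
                              rbind(c(0, 0, 0), c(0.95, 0.2, 0),
                                    c(-0.47, 0.2, 0.82), c(-0.47, 0.2, -0.82))),
               ref = -3.1),
    H2O = list(mol = water_molecule(), ref = -53.4),
    CH3OH = list(mol = molecule(c("C", "O", "H", "H", "H", "H"),
                                rbind(c(0, 0, 0), c(1.41, 0, 0),
                                      c(1.72, -0.55, 0.70), c(-0.39, 1.0, 0),
                                      c(-0.39, -0.5, 0.88), c(-0.39, -0.5, -0.88))),
                 ref = -51.9)
  )
  for (nm in names(cases)) {
    o <- gas_opt_tight(nm, cases[[nm]]$mol)
    expect_true(o$converged, label = paste(nm, "optimization"))
    expect_equal(heat_of_formation(o$state), cases[[nm]]$ref, tolerance = 0.15,
                 label = paste(nm, "heat of formation"))
  }
  # PM3 equilibrium H2 bond length
  h2 <- gas_opt_tight("H2", cases$H2$mol)$molecule
  expect_equal(sqrt(sum((h2$coords[1, ] - h2$coords[2, ])^2)), 0.699,
               tolerance = 0.002)
})

test_that("electron count is conserved and the density is idempotent", {
  p <- pm3()
  st <- scf(load_fixture("A1"), p)
  expect_true(st$converged)
  expect_equal(sum(diag(st$P)), 8, tolerance = 1e-10)
  expect_equal(st$P %*% st$P / 2, st$P, tolerance = 1e-5)
})

test_that("DIIS changes the path, not the fixed point", {
  p <- pm3()
  for (id in c("A1", "O1")) {
    m <- load_fixture(id)
    e1 <- scf(m, p, scf_options(diis = TRUE))$total_energy
    e2 <- scf(m, p, scf_options(diis = FALSE, max_iter = 500))$total_energy
    expect_equal(e1, e2, tolerance = 1e-6, label = paste(id, "DIIS equivalence"))
  }
})

test_that("total energy is invariant under rigid motions", {
  p <- pm3()
  m <- load_fixture("A2")
  e0 <- scf(m, p)$total_energy
  # translation
  mt <- molecule(m$symbols, sweep(m$coords, 2, c(-5, 5, 5)), m$charge)
  expect_equal(scf(mt, p)$total_energy, e0, tolerance = 1e-7)
  # rotation
  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  Rot <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  mr <- molecule(m$symbols, m$coords %*% t(Rot), m$charge)
  expect_equal(scf(mr, p)$total_energy, e0, tolerance = 1e-7)
  # translation leaves the heat of formation unchanged to tight precision
  expect_equal(scf(mt, p)$heat_of_formation, scf(m, p)$heat_of_formation,
               tolerance = 1e-7)
})

test_that("non-convergence is flagged, not thrown, and downstream refuses it", {
  p <- pm3()
  st <- scf(water_molecule(), p, scf_options(max_iter = 2))
  expect_false(st$converged)
  expect_error(heat_of_formation(st), "not converged")
})

test_that("odd electron counts and bad inputs are rejected", {
  expect_error(molecule("H", matrix(0, 1, 3), charge = 0), "odd electron")
  expect_error(molecule("X", matrix(0, 1, 3), charge = 0), "unsupported")
  expect_error(molecule(c("H", "H"), matrix(0, 1, 3)), "n x 3")
})
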