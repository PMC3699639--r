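# optimizer, double-difference Hessians, harmonic frequencies and the
# frequency MAD statistic

quadratic_model <- function(K, x0) {
  # synthetic energy model: E = 1/2 (x-x0)' K (x-x0), gradient analytic
  structure(list(
    kind = "test",
    evaluate = function(mol, P0 = NULL, need_gradient = TRUE) {
      x <- as.numeric(sepcm:::coords_bohr(mol))
      E <- 0.5 * sum((x - x0) * (K %*% (x - x0))) * 27.21
      g <- matrix(K %*% (x - x0), ncol = 3, byrow = TRUE)
      list(ok = TRUE, energy = E, gradient = g,
           state = list(P = matrix(0, 1, 1)))
    }
  ), class = "sepcm_model")
}

test_that("double differences recover a quadratic Hessian exactly", {
  set.seed(11)
  A <- matrix(rnorm(36), 6)
  K <- crossprod(A) / 10
  x0 <- rnorm(6) / 2
  mol <- molecule(c("H", "H"), matrix(rnorm(6), 2, 3) + 3, charge = 0)
  hd <- hessian_double_difference(mol, quadratic_model(K, x0), step = 0.02)
  expect_lt(max(abs(hd$hessian - K)), 1e-9)
  expect_lt(hd$asym, 1e-9)
})

test_that("optimization from a converged minimum takes at most one step", {
  p <- pm3()
  o0 <- gas_opt_tight("H2O_grad", water_molecule())
  o <- optimize_geometry(o0$molecule, model_gas(p))
  expect_true(o$converged)
  expect_lte(o$steps, 1)
})

test_that("H2 optimizes to the published PM3 bond length from a bad start", {
  p <- pm3()
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.1)))
  o <- optimize_geometry(m, model_gas(p), threshold = 1e-5)
  expect_true(o$converged)
  d <- sqrt(sum((o$molecule$coords[1, ] - o$molecule$coords[2, ])^2))
  expect_equal(d, 0.699, tolerance = 0.002)
})

test_that("water has three real vibrations; rigid modes are clean", {
  p <- pm3()
  # rigid-mode purity needs a tight SCF and a small displacement: the
  # rotational contamination of a double-difference Hessian scales linearly
  # with the step (cubic anharmonicity)
  tight <- structure(list(kind = "gas", evaluate = function(mol, P0 = NULL,
                                                            need_gradient = TRUE) {
    st <- scf(mol, p, scf_options(energy_tol = 1e-11, density_tol = 1e-9),
              P0 = P0)
    g <- if (need_gradient) total_gradient(mol, p, st)$gradient else NULL
    list(ok = st$converged, energy = st$total_energy, gradient = g, state = st)
  }), class = "sepcm_model")
  o <- optimize_geometry(water_molecule(), tight, threshold = 1e-6,
                         max_steps = 500)
  hd <- hessian_double_difference(o$molecule, tight, step = 0.002)
  expect_lt(hd$asym, 1e-4)
  fr <- frequencies(hd$hessian, o$molecule)
  expect_identical(length(fr$frequencies), 3L)
  expect_identical(fr$imaginary_count, 0L)
  expect_true(all(fr$frequencies > 1000))
  expect_lt(max(fr$rigid), 5)    # projection completeness at a tight minimum
  # the conventional 0.01 bohr step gives the same vibrational frequencies
  hd2 <- hessian_double_difference(o$molecule, model_gas(p))
  fr2 <- frequencies(hd2$hessian, o$molecule)
  expect_equal(fr2$frequencies, fr$frequencies, tolerance = 1e-3)
})

test_that("diatomic frequency agrees with the 1D curvature oracle", {
  p <- pm3()
  o <- gas_opt_tight("H2", molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.75))))
  hd <- hessian_double_difference(o$molecule, model_gas(p))
  fr <- frequencies(hd$hessian, o$molecule)
  expect_identical(length(fr$frequencies), 1L)
  # independent 1D oracle: curvature of E(d) along the bond
  d0 <- sqrt(sum((o$molecule$coords[1, ] - o$molecule$coords[2, ])^2)) / 0.529167
  e_at <- function(d) {
    m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, d * 0.529167)))
    scf(m, p, scf_options(energy_tol = 1e-11, density_tol = 1e-9))$total_energy / 27.21
  }
  h <- 0.01
  k <- (e_at(d0 + h) - 2 * e_at(d0) + e_at(d0 - h)) / h^2    # hartree/bohr^2
  mu <- (1.007825 / 2) / (1 / 1822.888486)                    # reduced mass, m_e
  nu_ref <- sqrt(k / mu) * 219474.63
  expect_equal(fr$frequencies[1], nu_ref, tolerance = 5 / nu_ref)
})

test_that("a free atom has an empty vibrational set", {
  fr <- frequencies(matrix(0, 3, 3), molecule("O", matrix(0, 1, 3), 0))
  expect_identical(length(fr$frequencies), 0L)
})

test_that("frequency MAD arithmetic, pairing and imaginary-mode handling", {
  expect_equal(as.numeric(mad_frequencies(c(100, 200), c(100, 200))), 0)
  expect_equal(as.numeric(mad_frequencies(c(100, 200), c(110, 190))), 10)
  # permutation safety: sorting inside makes input order irrelevant
  expect_equal(as.numeric(mad_frequencies(c(200, 100), c(190, 110))), 10)
  # imaginary modes (negative) are excluded, with counts attached
  m <- mad_frequencies(c(-50, 100, 200), c(105, 195))
  expect_equal(as.numeric(m), 5)
  expect_identical(attr(m, "imaginary_solvated"), 1L)
  expect_error(mad_frequencies(c(100, 200, 300), c(100, 200)), "counts differ")
})
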