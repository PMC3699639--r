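# PCM gradients: analytic surface-potential derivatives against finite
# differences, the cavity-area term, translational sum rules and the total
# gradient against full finite differences of the total energy

fd_potential <- function(fn, mol, cav, atom, h = 1e-5) {
  # central difference with the cavity rebuilt (tesserae ride rigidly)
  out <- array(0, c(length(cav$area_bohr2), 3))
  cb <- t(sepcm:::coords_bohr(mol))
  for (c in 1:3) {
    for (sgn in c(1, -1)) {
      cc <- cb
      cc[atom, c] <- cc[atom, c] + sgn * h
      mm <- molecule(mol$symbols, cc * 0.529167, mol$charge)
      cavd <- cavity_displacement_rebuild(cav, mm)
      stopifnot(length(cavd$area_bohr2) == length(cav$area_bohr2))
      out[, c] <- out[, c] + sgn * fn(mm, cavd) / (2 * h)
    }
  }
  out
}

test_that("analytic nuclear-potential derivative matches finite differences", {
  p <- pm3()
  m <- load_fixture("A2")   # 8-atom fixture
  cav <- tessellate_gepol(m, 60)
  for (atom in c(1, 4)) {
    ga <- nuclear_potential_derivative(m, p, cav, atom)
    gf <- fd_potential(function(mm, cavd) {
      suppressWarnings(nuclear_potential(mm, p, cavd))
    }, m, cav, atom)
    expect_lt(max(abs(ga - gf)), 1e-7)
  }
})

test_that("analytic electronic-potential derivative matches finite differences", {
  p <- pm3()
  m <- load_fixture("A2")
  cav <- tessellate_gepol(m, 60)
  st <- scf(m, p)
  for (atom in c(2, 5)) {
    ga <- electronic_potential_derivative(st$P, m, p, cav, atom)
    gf <- fd_potential(function(mm, cavd) {
      electronic_potential(st$P, mm, p, cavd)
    }, m, cav, atom)
    expect_lt(max(abs(ga - gf)), 1e-6)
  }
})

test_that("local-frame zero patterns survive in the integral derivatives", {
  p <- pm3()
  b <- tessera_integrals("C", c(0, 0, 4), p)
  # s-px and s-py stay zero under a z displacement
  expect_equal(b$dT[2, 3], 0, tolerance = 1e-14)
  expect_equal(b$dT[3, 3], 0, tolerance = 1e-14)
  expect_true(abs(b$dT[4, 3]) > 0)
})

test_that("cavity-area term vanishes for rigid translations", {
  p <- pm3()
  m <- load_fixture("A1")
  pcmc <- pcm_context(m)
  st <- scf(m, p, pcm = pcmc)
  res <- suppressWarnings(
    cavity_term_gradient(st$q, pcmc$cavity, m, pcmc$f))
  # translational sum rule on the area term itself
  expect_lt(max(abs(colSums(res$gradient))), 1e-5)
  expect_error(
    cavity_term_gradient(st$q, pcmc$cavity, m, pcmc$f, mode = "analytic_gb"),
    "numerical")
})

test_that("gas-phase limit: zero dielectric response leaves only the core", {
  p <- pm3()
  m <- load_fixture("A1")
  pcmc <- pcm_context(m, solvent_model(1))
  st <- scf(m, p, pcm = pcmc)
  tg <- suppressWarnings(total_gradient(m, p, st, pcm = NULL))
  # with f = 0 the charges vanish and the PCM energy is the gas energy
  expect_equal(max(abs(st$q)), 0, tolerance = 1e-14)
  stg <- scf(m, p)
  expect_equal(st$total_energy, stg$total_energy, tolerance = 1e-8)
  tgg <- total_gradient(m, p, stg)
  expect_equal(tg$gradient, tgg$gradient, tolerance = 1e-10)
})

test_that("assembled PCM gradient matches full finite differences", {
  p <- pm3()
  solv <- solvent_model()
  for (id in c("A1", "O1")) {
    m <- pipeline(id)$gas_opt$molecule
    pcmc <- pcm_context(m, solv, n_per_sphere = 60)
    st <- scf(m, p, pcm = pcmc,
              options = scf_options(energy_tol = 1e-10, density_tol = 1e-8))
    tg <- suppressWarnings(total_gradient(m, p, st, pcmc))
    frame <- pcmc$cavity$frame
    efn <- function(mm) {
      scf(mm, p, pcm = pcm_context(mm, solv, 60, frame = frame),
          options = scf_options(energy_tol = 1e-10, density_tol = 1e-8),
          P0 = st$P)$total_energy
    }
    gfd <- numerical_gradient(efn, m, step = 2e-4)
    expect_lt(max(abs(tg$gradient - gfd)), 1e-4)
    # translational sum rule for the assembled gradient
    expect_lt(max(abs(colSums(tg$gradient))), 1e-5)
  }
})
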