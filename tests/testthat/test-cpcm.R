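# C-PCM electrostatics: matrix structure, dielectric scaling, surface
# potentials, ASC solvers, Fock coupling and the free energy, with the Born
# model and Gauss's law as analytic oracles

single_sphere_cavity <- function(R_ang = 2.0, np = 960) {
  tessellate_gepol(molecule("O", matrix(0, 1, 3), 0), n_per_sphere = np,
                   radii_table = c(O = R_ang / 1.2), scale = 1.2)
}

test_that("C-PCM matrix elements and definiteness", {
  # off-diagonal: inverse distance in au for two same-sphere tesserae 2 A apart
  pos <- rbind(c(0, 0, 0), c(2 / 0.529167, 0, 0))
  cavf <- list(pos_bohr = pos, area_bohr2 = c(4 * pi, 4 * pi),
               sphere_row = c(1L, 1L))
  D <- build_cpcm_matrix(cavf, kdiag = 1.0694)
  expect_equal(D[1, 2], 0.529167 / 2, tolerance = 1e-10)
  # diagonal with a_i = 4 pi: exactly the diagonal constant
  expect_equal(D[1, 1], 1.0694, tolerance = 1e-12)
  expect_equal(D, t(D))
  # coincident tesserae are a degenerate cavity
  cavbad <- list(pos_bohr = rbind(c(0, 0, 0), c(0, 0, 1e-10)),
                 area_bohr2 = c(1, 1), sphere_row = c(1L, 1L))
  expect_error(build_cpcm_matrix(cavbad), "degenerate")
  # full 960-tessera sphere: positive definite (Cholesky succeeds)
  Ds <- build_cpcm_matrix(single_sphere_cavity())
  expect_silent(chol(Ds))
})

test_that("dielectric scaling function", {
  expect_equal(dielectric_scale(solvent_model(1)), 0)
  expect_equal(dielectric_scale(solvent_model(1e9)), 1, tolerance = 1e-8)
  expect_equal(dielectric_scale(solvent_model(78.39)), 0.98724, tolerance = 1e-5)
  expect_gt(dielectric_scale(solvent_model(80)),
            dielectric_scale(solvent_model(20)))
  expect_error(solvent_model(0.5), "epsilon")
  expect_equal(dielectric_scale(solvent_model(78.39, "eps+0.5")),
               77.39 / 78.89, tolerance = 1e-10)
})

test_that("nuclear potential at the surface", {
  p <- pm3()
  m <- load_fixture("A1")
  cav <- tessellate_gepol(m, 60)
  v <- nuclear_potential(m, p, cav)
  expect_true(all(v > 0))          # all-positive cores
  expect_identical(length(v), length(cav$area_bohr2))
  # neutral far field: total (nuclear + electronic) potential decays fast
  mw <- gas_opt_tight("H2O_grad", water_molecule())$molecule
  stw <- scf(mw, p)
  far <- list(pos_bohr = matrix(c(100 / .529167, 0, 0), 1, 3),
              area_bohr2 = 1, sphere_row = 1L)
  vtot <- nuclear_potential(mw, p, far) + electronic_potential(stw$P, mw, p, far)
  expect_lt(abs(vtot), 1e-4)
})

test_that("tessera integrals: symmetry, limits and the point-charge oracle", {
  p <- pm3()
  # hydrogen: pure monopole
  bH <- tessera_integrals("H", c(0, 0, 3), p)
  expect_equal(bH$T[1], 1 / 3, tolerance = 1e-12)
  expect_true(all(bH$T[2:10] == 0))
  # carbon with the tessera on +z: local-frame zero pattern survives rotation
  bC <- tessera_integrals("C", c(0, 0, 5), p)
  expect_equal(bC$T[2], 0, tolerance = 1e-14)  # s-px
  expect_equal(bC$T[3], 0, tolerance = 1e-14)  # s-py
  expect_gt(abs(bC$T[4]), 0)                   # s-pz
  # far field: R*V_ss -> 1 exactly, and R^2*V_spz -> D1 as (D1/R)^2 -> 0
  R <- 20
  b <- tessera_integrals("C", c(0, 0, R), p)
  expect_equal(R * b$T[1], 1, tolerance = 1e-6)
  expect_equal(R^2 * b$T[4], p$C$dd, tolerance = 2 * (p$C$dd / R)^2)
  R2 <- 200
  b2 <- tessera_integrals("C", c(0, 0, R2), p)
  expect_equal(R2^2 * b2$T[4], p$C$dd, tolerance = 1e-4)
  # full block against the explicit point-charge configuration sums at a
  # generic direction; the rotated closed forms and the axis-bound
  # configurations agree up to O((D1/R)^2) finite-separation effects
  rv <- 20 * c(1, -2, 2) / 3
  got <- tessera_integrals("C", rv, p)$T
  ref <- brute_tessera_block(p$C$dd, p$C$qq, rv)
  expect_equal(as.numeric(got), as.numeric(ref), tolerance = 5e-3)
  # on the local axis the two routes coincide to machine precision
  gz <- tessera_integrals("C", c(0, 0, 20), p)$T
  rz <- brute_tessera_block(p$C$dd, p$C$qq, c(0, 0, 20))
  expect_equal(as.numeric(gz), as.numeric(rz), tolerance = 1e-10)
  # near-field warning
  expect_warning(tessera_integrals("C", c(0, 0, 0.5), p), "near-field|clamped")
  expect_error(tessera_integrals("C", c(0, 0, 0), p), "positive")
})

test_that("electronic potential contracts the density correctly", {
  p <- pm3()
  m <- load_fixture("A1")
  cav <- tessellate_gepol(m, 60)
  P0 <- matrix(0, 8, 8)
  expect_equal(electronic_potential(P0, m, p, cav),
               rep(0, length(cav$area_bohr2)))
  expect_error(electronic_potential(matrix(0, 3, 3), m, p, cav))
  # a converged cation has net positive area-weighted surface potential
  st <- scf(m, p)
  vtot <- nuclear_potential(m, p, cav) + electronic_potential(st$P, m, p, cav)
  expect_gt(sum(cav$area_bohr2 * vtot), 0)
})

test_that("ASC solution: Gauss's law and the Born oracle", {
  cav <- single_sphere_cavity(2.0, 960)
  f <- dielectric_scale(solvent_model(78.39))
  V <- 1 / sqrt(rowSums(cav$pos_bohr^2))    # unit point charge at the centre
  D <- build_cpcm_matrix(cav)
  q <- solve_asc(D, V, f, "direct")
  expect_equal(sum(q), -f, tolerance = 0.015)
  dG <- electrostatic_free_energy(q, V)
  born <- -0.5 * f / (2 / 0.529167) * 627.49
  expect_equal(dG, born, tolerance = abs(born) * 0.02)
  # refinement moves Gauss's law closer to exact
  cav60 <- single_sphere_cavity(2.0, 60)
  V60 <- 1 / sqrt(rowSums(cav60$pos_bohr^2))
  q60 <- solve_asc(build_cpcm_matrix(cav60), V60, f, "direct")
  expect_lt(abs(sum(q) + f), abs(sum(q60) + f))
  # V = 0 -> q = 0, and the vacuum limit
  expect_equal(solve_asc(D, rep(0, nrow(D)), f, "direct"), rep(0, nrow(D)))
  expect_equal(electrostatic_free_energy(numeric(0), numeric(0)), 0)
  expect_error(electrostatic_free_energy(1, c(1, 2)), "lengths differ")
})

test_that("direct and iterative ASC solvers agree per charge", {
  cav <- tessellate_gepol(load_fixture("A1"), 240)
  m <- load_fixture("A1")
  p <- pm3()
  V <- nuclear_potential(m, p, cav)
  f <- dielectric_scale(solvent_model())
  qd <- solve_asc(build_cpcm_matrix(cav), V, f, "direct")
  qi <- solve_asc(NULL, V, f, "iterative", cavity = cav, tol = 1e-10)
  expect_lt(max(abs(qd - qi)), 1e-6)
})

test_that("PCM Fock coupling stabilizes a cation variationally", {
  p <- pm3()
  # one-term sum: single H distribution against q = -1 at 1 bohr
  cav1 <- list(pos_bohr = matrix(c(0, 0, 1), 1, 3), area_bohr2 = 1,
               sphere_row = 1L)
  mH <- molecule("H", matrix(0, 1, 3), charge = 1)
  Fp <- pcm_fock_contribution(-1, mH, p, cav1)
  expect_equal(Fp[1, 1], 27.21, tolerance = 1e-10)  # +1 au, repulsive, in eV
  # q = 0 is the gas-phase limit
  m <- load_fixture("A1")
  cav <- tessellate_gepol(m, 60)
  expect_equal(pcm_fock_contribution(rep(0, length(cav$area_bohr2)), m, p, cav),
               matrix(0, 8, 8))
  # full system: solvation lowers the total energy of a cation
  stg <- scf(m, p)
  sts <- scf(m, p, pcm = pcm_context(m))
  expect_true(sts$converged)
  expect_lt(sts$total_energy, stg$total_energy)
  expect_lt(sts$dG_el, 0)
})

test_that("solvated free energy is frame invariant and self-consistent", {
  p <- pm3()
  m <- load_fixture("A1")
  st <- scf(m, p, pcm = pcm_context(m))
  th <- 0.9; ax <- c(3, 1, -2) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  Rot <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  mr <- molecule(m$symbols, sweep(m$coords %*% t(Rot), 2, c(2, -1, 3)), m$charge)
  str <- scf(mr, p, pcm = pcm_context(mr))
  expect_equal(str$dG_el, st$dG_el, tolerance = 0.01)
  # recomputing q from the converged density does not move dG_el
  cav <- st$pcm$cavity
  V <- nuclear_potential(m, p, cav) + electronic_potential(st$P, m, p, cav)
  q2 <- solve_asc(build_cpcm_matrix(cav), V, st$pcm$f, "direct")
  dG2 <- electrostatic_free_energy(q2, V)
  expect_equal(dG2, st$dG_el, tolerance = 1e-6)
})

test_that("vacuum dielectric gives a zero solvation magnitude by construction", {
  res <- suppressWarnings(solvation_free_energy(
    load_fixture("A1"), params = pm3(), solvent = solvent_model(1),
    n_tess_sp = 60))
  expect_equal(res$magnitude, 0, tolerance = 1e-8)
  expect_equal(res$dG_el, 0, tolerance = 1e-12)
})
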