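#' SCF options
#'
#' @param max_iter maximum SCF iterations.
#' @param energy_tol convergence threshold on the total energy change (eV).
#' @param density_tol convergence threshold on the largest density-matrix
#'   element change.
#' @param diis use DIIS convergence acceleration.
#' @param diis_size DIIS subspace size.
#' @return a list of options.
#' @export
scf_options <- function(max_iter = 200L, energy_tol = 1e-7, density_tol = 1e-6,
                        diis = TRUE, diis_size = 8L) {
  list(max_iter = as.integer(max_iter), energy_tol = energy_tol,
       density_tol = density_tol, diis = diis, diis_size = as.integer(diis_size))
}

#' Restricted closed-shell NDDO SCF
#'
#' Iterates the NDDO Fock equations for a closed-shell molecule. When a
#' `pcm` context is supplied, the one-electron solvent term is rebuilt from
#' the current density every iteration (fully coupled C-PCM) and the total
#' energy includes the electrostatic solute-solvent free energy.
#'
#' @param mol a [molecule()].
#' @param params an [load_parameters()] set covering all elements present.
#' @param options see [scf_options()].
#' @param pcm optional solvent context from [pcm_context()].
#' @param P0 optional starting density matrix (warm start).
#' @return an `scf_result` with density, Fock and orbital data, energies in eV,
#'   the heat of formation in kcal/mol, and (with PCM) the apparent surface
#'   charges `q`, surface potential `V` and `dG_el` in kcal/mol.
#' @export
scf <- function(mol, params, options = scf_options(), pcm = NULL, P0 = NULL) {
  args <- cpp_param_args(mol, params)
  nelec <- n_electrons(mol)
  pcm_list <- NULL
  if (!is.null(pcm)) {
    pcm_list <- list(tess_pos = t(pcm$cavity$pos_bohr),
                     tess_area = pcm$cavity$area_bohr2,
                     tess_sphere = pcm$cavity$sphere_row,
                     f = pcm$f, kdiag = pcm$kdiag,
                     solver = pcm$solver, cg_tol = pcm$cg_tol)
  }
  res <- cpp_scf(coords_bohr(mol), args$plist, args$ielem, nelec,
                 options, pcm_list, P0)
  res$molecule <- mol
  res$method <- params$.method
  eisol <- sum(vapply(mol$symbols, function(s) params[[s]]$eisol, 0))
  eheat <- sum(vapply(mol$symbols, function(s) params[[s]]$eheat, 0))
  res$heat_of_formation <- (res$total_energy - eisol) * KCAL_PER_EV + eheat
  if (!is.null(pcm)) {
    res$dG_el <- res$gpcm_au * KCAL_PER_HARTREE
    res$pcm <- pcm
  }
  class(res) <- "scf_result"
  res
}

#' @export
print.scf_result <- function(x, ...) {
  cat("<scf_result>", if (x$converged) "converged" else "NOT CONVERGED",
      "in", x$iterations, "iterations\n")
  cat("  total energy      ", sprintf("%.6f eV", x$total_energy), "\n")
  cat("  heat of formation ", sprintf("%.4f kcal/mol", x$heat_of_formation), "\n")
  if (!is.null(x$dG_el)) {
    cat("  dG_el (PCM)       ", sprintf("%.4f kcal/mol", x$dG_el), "\n")
  }
  invisible(x)
}

#' Heat of formation from a converged SCF state
#'
#' The semi-empirical total energy referenced to the isolated-atom electronic
#' energies and experimental atomic heats of formation.
#'
#' @param state an `scf_result`.
#' @return kcal/mol.
#' @export
heat_of_formation <- function(state) {
  if (!isTRUE(state$converged)) {
    stop("SCF state is not converged; heat of formation undefined")
  }
  state$heat_of_formation
}

#' Core (one-electron) NDDO Hamiltonian
#'
#' Diagonal blocks carry the one-center U terms plus two-center
#' core-attraction sums; interatomic blocks are resonance terms
#' \eqn{\beta \cdot S} from exact Slater overlaps.
#'
#' @inheritParams scf
#' @return list with the symmetric matrix `H` (eV) and the core-core
#'   repulsion energy `enuc` (eV).
#' @export
build_core_hamiltonian <- function(mol, params) {
  check_geometry(mol)
  args <- cpp_param_args(mol, params)
  cpp_build_hcore(coords_bohr(mol), args$plist, args$ielem)
}

check_geometry <- function(mol) {
  d <- as.matrix(stats::dist(mol$coords))
  diag(d) <- Inf
  if (any(d < 1e-3)) stop("overlapping nuclei: interatomic distance < 1e-3 A")
  invisible(mol)
}

#' Two-center two-electron integral block
#'
#' The full 10 x 10 block of \eqn{(\mu\nu|\lambda\sigma)} integrals (eV) for
#' the one-center pair distributions of two atoms, in the molecular frame.
#' Row/column order: ss, s-px, s-py, s-pz, xx, xy, xz, yy, yz, zz.
#'
#' @param elem_a,elem_b element symbols.
#' @param rab 3-vector from atom A to atom B, Angstrom.
#' @param params parameter set.
#' @return 10 x 10 matrix (eV); entries involving p functions are zero for
#'   hydrogen.
#' @export
two_center_repulsion_integrals <- function(elem_a, elem_b, rab, params) {
  if (sqrt(sum(rab^2)) < 1e-6) stop("atoms must be distinct")
  args_a <- cpp_param_args(molecule(elem_a, matrix(0, 1, 3), charge = elem_charge_dummy(elem_a)), params)
  args_b <- cpp_param_args(molecule(elem_b, matrix(0, 1, 3), charge = elem_charge_dummy(elem_b)), params)
  cpp_pair_repulsion(args_a$plist[[args_a$ielem[1]]],
                     args_b$plist[[args_b$ielem[1]]],
                     angstrom_to_bohr(as.numeric(rab)))
}

# single atoms of N/H etc. have odd electron counts; the charge is irrelevant
# for parameter lookup, so neutralize the parity check
elem_charge_dummy <- function(el) {
  if (valence_electrons[[el]] %% 2 == 0) 0L else 1L
}

#' Core-core repulsion energy
#'
#' Pairwise screened monopole repulsion (MNDO form), with the AM1/PM3 Gaussian
#' corrections when the parameter set carries them.
#'
#' @inheritParams scf
#' @return energy in eV.
#' @export
core_core_repulsion <- function(mol, params) {
  args <- cpp_param_args(mol, params)
  n <- length(mol$symbols)
  if (n < 2) return(0)
  e <- 0
  cb <- coords_bohr(mol)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      r <- sqrt(sum((cb[, a] - cb[, b])^2))
      e <- e + cpp_core_core(args$plist[[args$ielem[a]]],
                             args$plist[[args$ielem[b]]], r)
    }
  }
  e
}

#' Numerical gradient of an energy function
#'
#' Central differences with one displacement pair per Cartesian component.
#'
#' @param energy_fn function(molecule) -> energy (eV); must succeed at every
#'   displaced geometry.
#' @param mol a [molecule()].
#' @param step displacement, bohr.
#' @return n x 3 matrix of derivatives in hartree/bohr.
#' @export
numerical_gradient <- function(energy_fn, mol, step = 1e-3) {
  n <- length(mol$symbols)
  g <- matrix(0, n, 3)
  cb <- coords_bohr(mol)
  for (a in seq_len(n)) {
    for (c in 1:3) {
      cp <- cb; cp[c, a] <- cp[c, a] + step
      cm <- cb; cm[c, a] <- cm[c, a] - step
      ep <- tryCatch(energy_fn(with_coords_bohr(mol, cp)), error = function(e) {
        stop("energy evaluation failed at displacement (atom ", a,
             ", coord ", c, ", +", step, " bohr): ", conditionMessage(e))
      })
      em <- tryCatch(energy_fn(with_coords_bohr(mol, cm)), error = function(e) {
        stop("energy evaluation failed at displacement (atom ", a,
             ", coord ", c, ", -", step, " bohr): ", conditionMessage(e))
      })
      g[a, c] <- (ep - em) / (2 * step) / EV_PER_HARTREE
    }
  }
  g
}

# fast path used by the optimizer: gas-phase gradient at fixed converged
# density (variational short cut; pairwise incremental energies in C++)
core_gradient_fixed_density <- function(mol, params, P, step = 1e-3) {
  args <- cpp_param_args(mol, params)
  g <- cpp_core_gradient_fd(coords_bohr(mol), args$plist, args$ielem, P, step)
  matrix(g, ncol = 3, byrow = TRUE)
}
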