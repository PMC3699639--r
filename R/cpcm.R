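#' Solvent model for C-PCM
#'
#' @param epsilon relative permittivity (>= 1). Default 78.39 (water).
#' @param f_form dielectric scaling function: `"eps"` for
#'   \eqn{f(\epsilon) = (\epsilon-1)/\epsilon} (default) or `"eps+0.5"` for
#'   \eqn{(\epsilon-1)/(\epsilon+0.5)}.
#' @return object of class `sepcm_solvent`.
#' @export
solvent_model <- function(epsilon = 78.39, f_form = c("eps", "eps+0.5")) {
  if (!is.numeric(epsilon) || epsilon < 1) {
    stop("epsilon must be >= 1")
  }
  f_form <- match.arg(f_form)
  structure(list(epsilon = epsilon, f_form = f_form), class = "sepcm_solvent")
}

#' Dielectric scaling factor of the conductor-like model
#' @param solvent a [solvent_model()].
#' @return f in [0, 1); 0 for vacuum, -> 1 for a conductor.
#' @export
dielectric_scale <- function(solvent) {
  eps <- solvent$epsilon
  switch(solvent$f_form,
         "eps" = (eps - 1) / eps,
         "eps+0.5" = (eps - 1) / (eps + 0.5))
}

#' C-PCM matrix over the tesserae
#'
#' Diagonal `kdiag * sqrt(4*pi/a_i)`, off-diagonal inverse inter-tessera
#' distances; symmetric positive definite for a valid cavity. Atomic units.
#'
#' @param cavity a [tessellate_gepol()] cavity.
#' @param kdiag diagonal constant (standard conductor-like choice 1.0694).
#' @return dense symmetric matrix (au).
#' @export
build_cpcm_matrix <- function(cavity, kdiag = 1.0694) {
  cpp_build_dmatrix(t(cavity$pos_bohr), cavity$area_bohr2, cavity$sphere_row,
                    kdiag)
}

#' Nuclear potential at the tesserae
#'
#' \eqn{V_i = \sum_A Z_A / |s_i - R_A|} with the NDDO valence core charges.
#'
#' @param mol a [molecule()].
#' @param params parameter set (for the core charges).
#' @param cavity cavity.
#' @return vector (au). A warning is raised if a tessera sits inside 0.1 bohr
#'   of a nucleus.
#' @export
nuclear_potential <- function(mol, params, cavity) {
  args <- cpp_param_args(mol, params)
  d <- apply(cavity$pos_bohr, 1, function(s) {
    min(sqrt(colSums((coords_bohr(mol) - s)^2)))
  })
  if (any(d < 0.1)) {
    warning(sum(d < 0.1), " tessera(e) within 0.1 bohr of a nucleus; ",
            "potential clamped")
  }
  as.numeric(cpp_nuclear_potential(coords_bohr(mol), args$plist, args$ielem,
                                   t(cavity$pos_bohr)))
}

#' Tessera interaction integrals of one atom
#'
#' The ten unique integrals between the one-center NDDO charge distributions
#' of an atom and a unit charge at a tessera, rotated onto the molecular frame
#' by the direction cosines of the atom-to-tessera vector. The Klopman-Ohno
#' additive terms are zero for these integrals; effective distances are
#' floored at 0.1 bohr (a warning flags the near field).
#'
#' @param element element symbol of the atom carrying the basis functions.
#' @param rvec 3-vector from atom to tessera, bohr.
#' @param params parameter set.
#' @return list with `T` (10 integrals, au; order ss, s-px, s-py, s-pz, xx,
#'   xy, xz, yy, yz, zz) and `dT` (10 x 3 derivative w.r.t. `rvec`).
#' @export
tessera_integrals <- function(element, rvec, params) {
  r <- sqrt(sum(rvec^2))
  if (r <= 0) stop("atom-tessera distance must be positive")
  e <- params[[element]]
  if (is.null(e)) stop("no parameters for element ", element)
  if (r < max(e$dd, 2 * e$qq)) {
    warning("tessera inside the point-multipole extent (R = ", signif(r, 4),
            " bohr); clamped near-field branch active")
  }
  dummy <- molecule(element, matrix(0, 1, 3), charge = elem_charge_dummy(element))
  args <- cpp_param_args(dummy, params)
  cpp_tessera_block(args$plist[[args$ielem[1]]], as.numeric(rvec))
}

#' Electronic potential at the tesserae
#'
#' \eqn{V^{el}_i = -\sum_{\mu\nu} P_{\mu\nu} \langle\mu\nu\rangle_i}
#' (one-center NDDO pairs only).
#'
#' @param P density matrix.
#' @param mol molecule.
#' @param params parameter set.
#' @param cavity cavity.
#' @return vector (au).
#' @export
electronic_potential <- function(P, mol, params, cavity) {
  args <- cpp_param_args(mol, params)
  ti <- cpp_tessera_integrals(coords_bohr(mol), args$plist, args$ielem,
                              t(cavity$pos_bohr))
  pv <- pack_density_r(P, mol, params)
  if (length(pv) != ncol(ti$T)) stop("density dimension mismatch")
  as.numeric(-ti$T %*% pv)
}

# packed one-center density vector matching the tessera-integral columns
pack_density_r <- function(P, mol, params) {
  pidx <- rbind(c(1, 1), c(1, 2), c(1, 3), c(1, 4), c(2, 2), c(2, 3),
                c(2, 4), c(3, 3), c(3, 4), c(4, 4))
  off <- 0
  pv <- numeric(0)
  for (s in mol$symbols) {
    norb <- params[[s]]$norb
    np <- if (norb == 4) 10 else 1
    for (t in seq_len(np)) {
      i <- off + pidx[t, 1]
      j <- off + pidx[t, 2]
      pv <- c(pv, if (i == j) P[i, j] else 2 * P[i, j])
    }
    off <- off + norb
  }
  pv
}

#' Solve for the apparent surface charges
#'
#' \eqn{q = -f D^{-1} V}, either by a direct (Cholesky) solve or by
#' Jacobi-preconditioned conjugate gradients on the residual norm.
#'
#' @param D C-PCM matrix, or `NULL` with `cavity` given (iterative mode can
#'   run matrix-free).
#' @param V total surface potential (au).
#' @param f dielectric scaling factor.
#' @param mode `"direct"` or `"iterative"`.
#' @param cavity cavity (needed for matrix-free iterative mode).
#' @param tol iterative residual tolerance.
#' @param kdiag diagonal constant.
#' @return vector of charges (au).
#' @export
solve_asc <- function(D = NULL, V, f, mode = c("direct", "iterative"),
                      cavity = NULL, tol = 1e-8, kdiag = 1.0694) {
  mode <- match.arg(mode)
  rhs <- -f * V
  if (mode == "direct") {
    if (is.null(D)) D <- build_cpcm_matrix(cavity, kdiag)
    ch <- chol(D)
    return(as.numeric(backsolve(ch, forwardsolve(t(ch), rhs))))
  }
  if (is.null(cavity)) stop("iterative mode needs the cavity")
  res <- cpp_cg_asc(t(cavity$pos_bohr), cavity$area_bohr2, cavity$sphere_row,
                    kdiag, rhs, numeric(length(rhs)), tol, 5000L)
  if (!res$converged) {
    stop("ASC conjugate-gradient solver did not converge (residual after ",
         res$iterations, " sweeps)")
  }
  as.numeric(res$q)
}

#' PCM one-electron Fock contribution
#'
#' \eqn{F^{PCM}_{\mu\nu} = -\sum_i q_i \langle\mu\nu\rangle_i}; negative
#' induced charges around a cation stabilize the system.
#'
#' @param q apparent surface charges (au).
#' @param mol,params,cavity as elsewhere.
#' @return symmetric basis x basis matrix (eV).
#' @export
pcm_fock_contribution <- function(q, mol, params, cavity) {
  args <- cpp_param_args(mol, params)
  ti <- cpp_tessera_integrals(coords_bohr(mol), args$plist, args$ielem,
                              t(cavity$pos_bohr))
  fv <- as.numeric(crossprod(ti$T, q))
  nbf <- sum(ifelse(mol$symbols == "H", 1, 4))
  Fp <- matrix(0, nbf, nbf)
  pidx <- rbind(c(1, 1), c(1, 2), c(1, 3), c(1, 4), c(2, 2), c(2, 3),
                c(2, 4), c(3, 3), c(3, 4), c(4, 4))
  col_atom <- ti$col_atom + 1L
  col_pair <- ti$col_pair + 1L
  offs <- cumsum(c(0, ifelse(mol$symbols == "H", 1, 4)))
  for (c in seq_along(fv)) {
    a <- col_atom[c]
    i <- offs[a] + pidx[col_pair[c], 1]
    j <- offs[a] + pidx[col_pair[c], 2]
    Fp[i, j] <- Fp[i, j] - fv[c] * EV_PER_HARTREE
    if (i != j) Fp[j, i] <- Fp[i, j]
  }
  Fp
}

#' Electrostatic solute-solvent free energy
#'
#' \eqn{\Delta G_{el} = \tfrac12 \sum_i q_i V_i}, converted to kcal/mol.
#'
#' @param q apparent surface charges (au).
#' @param V surface potential (au).
#' @return kcal/mol (non-positive for self-consistent solutions).
#' @export
electrostatic_free_energy <- function(q, V) {
  if (length(q) != length(V)) stop("q and V lengths differ")
  0.5 * sum(q * V) * KCAL_PER_HARTREE
}

#' Assemble a PCM context for the SCF
#'
#' Couples a solvent model to a cavity built for the current geometry.
#'
#' @param mol molecule.
#' @param solvent a [solvent_model()].
#' @param n_per_sphere tesserae per sphere (60, 240, 960).
#' @param radii_table,scale,hydrogen_spheres cavity options, see
#'   [assign_radii()].
#' @param solver ASC solver inside the SCF: `"direct"` (Cholesky, cached) or
#'   `"iterative"` (matrix-free conjugate gradients). `"auto"` picks direct
#'   below 4000 tesserae.
#' @param kdiag diagonal constant of the C-PCM matrix.
#' @param cg_tol iterative solver tolerance.
#' @param frame optional fixed polyhedron frame (see [tessellate_gepol()]).
#' @return object of class `sepcm_pcm`.
#' @export
pcm_context <- function(mol, solvent = solvent_model(), n_per_sphere = 60,
                        radii_table = BONDI_RADII, scale = 1.2,
                        hydrogen_spheres = TRUE,
                        solver = c("auto", "direct", "iterative"),
                        kdiag = 1.0694, cg_tol = 1e-8, frame = NULL) {
  solver <- match.arg(solver)
  cavity <- tessellate_gepol(mol, n_per_sphere = n_per_sphere,
                             radii_table = radii_table, scale = scale,
                             hydrogen_spheres = hydrogen_spheres, frame = frame)
  if (solver == "auto") {
    solver <- if (length(cavity$area_bohr2) <= 4000) "direct" else "iterative"
  }
  structure(list(cavity = cavity, solvent = solvent,
                 f = dielectric_scale(solvent), kdiag = kdiag,
                 solver = solver, cg_tol = cg_tol),
            class = "sepcm_pcm")
}

#' @export
print.sepcm_pcm <- function(x, ...) {
  cat("<sepcm_pcm> eps =", x$solvent$epsilon, " f =", signif(x$f, 6),
      ";", length(x$cavity$area_bohr2), "tesserae;", x$solver, "solver\n")
  invisible(x)
}
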