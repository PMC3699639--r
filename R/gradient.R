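#' Derivative of the nuclear surface potential
#'
#' \eqn{\partial V^{nuc}_i/\partial x_A}: the direct field term plus, for
#' tesserae riding on sphere A, the rigid-translation term.
#'
#' @param mol,params,cavity as elsewhere.
#' @param atom_index 1-based atom.
#' @return tesserae x 3 matrix (au/bohr).
#' @export
nuclear_potential_derivative <- function(mol, params, cavity, atom_index) {
  args <- cpp_param_args(mol, params)
  cpp_nuclear_potential_derivative(coords_bohr(mol), args$plist, args$ielem,
                                   t(cavity$pos_bohr), cavity$sphere,
                                   as.integer(atom_index))
}

#' Derivative of the electronic surface potential at fixed density
#'
#' Analytic chain rule through the local-frame tessera integrals and the
#' direction cosines, including the rigid riding of sphere-A tesserae.
#'
#' @param P converged density matrix.
#' @param mol,params,cavity as elsewhere.
#' @param atom_index 1-based atom.
#' @return tesserae x 3 matrix (au/bohr).
#' @export
electronic_potential_derivative <- function(P, mol, params, cavity, atom_index) {
  args <- cpp_param_args(mol, params)
  cpp_electronic_potential_derivative(coords_bohr(mol), args$plist, args$ielem,
                                      P, t(cavity$pos_bohr), cavity$sphere,
                                      as.integer(atom_index))
}

#' Cavity (tessera-area) contribution to the PCM gradient
#'
#' The diagonal of the C-PCM matrix depends on the exposed tessera areas;
#' this term is \eqn{(1/2f)\, q^T (\partial D^{diag}/\partial x)\, q},
#' evaluated by central differences of deterministic cavity rebuilds. When a
#' tessera appears or vanishes inside the stencil (a tessellation
#' discontinuity) the step is halved up to three times and the component is
#' flagged rather than smoothed.
#'
#' @param q converged surface charges.
#' @param cavity cavity bound to `mol`.
#' @param mol molecule.
#' @param f dielectric scaling factor.
#' @param mode `"numerical"` (central differences of the rebuilt areas).
#' @param step displacement, bohr.
#' @param kdiag diagonal constant.
#' @return list with `gradient` (n x 3, au/bohr) and logical `flagged`.
#' @export
cavity_term_gradient <- function(q, cavity, mol, f, mode = "numerical",
                                 step = 1e-5, kdiag = 1.0694) {
  if (mode != "numerical") {
    stop("only the numerical cavity-term mode is implemented")
  }
  res <- cpp_area_term_gradient(t(cavity$centers_bohr), cavity$radii_bohr,
                                cavity$n_per_sphere, cavity$frame,
                                t(cavity$pos_bohr), cavity$area_bohr2,
                                cavity$sphere_row, cavity$tri, q, f, kdiag, step)
  n <- length(mol$symbols)
  g <- matrix(res$gradient, n, 3, byrow = TRUE)
  fl <- matrix(res$flagged == 1, n, 3, byrow = TRUE)
  if (any(fl)) {
    warning("tessellation discontinuity in the area-derivative stencil at ",
            sum(fl), " coordinate(s); flagged")
  }
  list(gradient = g, flagged = fl)
}

#' Total energy gradient
#'
#' Gas phase: central differences of the semi-empirical energy expression at
#' the fixed converged density (variational short cut). With PCM: that core
#' term plus the analytic solvent terms \eqn{q^T \partial V/\partial x}
#' (nuclear and electronic, tesserae riding rigidly on their spheres), the
#' analytic inter-sphere part of \eqn{(1/2f) q^T \partial D/\partial x q},
#' and the numerical tessera-area term.
#'
#' @param mol molecule.
#' @param params parameter set.
#' @param state converged `scf_result` at this geometry (gas or PCM).
#' @param pcm the `sepcm_pcm` context used for `state`, or NULL for gas phase.
#' @param step finite-difference step for the core term (bohr).
#' @param step_area finite-difference step for the tessera-area term (bohr);
#'   kept much smaller than `step` so the stencil samples a single smooth
#'   branch of the piecewise-smooth clipped areas.
#' @return list with `gradient` (n x 3, hartree/bohr), the per-term
#'   decomposition, and `flagged` area-stencil components.
#' @export
total_gradient <- function(mol, params, state, pcm = NULL, step = 1e-3,
                           step_area = 1e-5) {
  if (!isTRUE(state$converged)) stop("SCF not converged; gradient undefined")
  g_core <- core_gradient_fixed_density(mol, params, state$P, step)
  if (is.null(pcm) || pcm$f == 0) {
    # vacuum limit: no induced charge, the PCM terms are exactly zero
    return(list(gradient = g_core, core = g_core,
                flagged = matrix(FALSE, nrow(g_core), 3)))
  }
  args <- cpp_param_args(mol, params)
  cav <- pcm$cavity
  g_pcm <- cpp_pcm_gradient_analytic(coords_bohr(mol), args$plist, args$ielem,
                                     state$P, t(cav$pos_bohr), cav$sphere,
                                     state$q, pcm$f, cav$area_bohr2, pcm$kdiag)
  n <- length(mol$symbols)
  g_pcm <- matrix(g_pcm, n, 3, byrow = TRUE)
  area <- cavity_term_gradient(state$q, cav, mol, pcm$f, step = step_area,
                               kdiag = pcm$kdiag)
  g <- g_core + g_pcm + area$gradient
  list(gradient = g, core = g_core, field = g_pcm, cavity = area$gradient,
       flagged = area$flagged)
}

#' Write a per-term gradient decomposition to a text file
#' @param grad result of [total_gradient()].
#' @param mol molecule.
#' @param path output file.
#' @export
write_gradient_dump <- function(grad, mol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# total gradient decomposition (hartree/bohr)", con)
  for (term in intersect(c("core", "field", "cavity", "gradient"), names(grad))) {
    writeLines(paste0("## ", term), con)
    m <- grad[[term]]
    writeLines(sprintf("%-2s %15.9f %15.9f %15.9f", mol$symbols,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
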