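# Energy/gradient "models" used by the optimizer and the solvation pipeline:
# closures binding a parameter set (and optionally a solvent) that evaluate
# energy, gradient and SCF state at a geometry, threading the previous
# density through as a warm start.

#' Gas-phase energy model
#'
#' @param params parameter set.
#' @param options SCF options.
#' @return model object with an `evaluate(mol, P0)` closure.
#' @export
model_gas <- function(params, options = scf_options()) {
  structure(list(
    kind = "gas",
    params = params,
    evaluate = function(mol, P0 = NULL, need_gradient = TRUE) {
      st <- scf(mol, params, options, P0 = P0)
      if (!st$converged) {
        return(list(ok = FALSE, state = st))
      }
      g <- if (need_gradient) total_gradient(mol, params, st)$gradient else NULL
      list(ok = TRUE, energy = st$total_energy, gradient = g, state = st)
    }
  ), class = "sepcm_model")
}

#' Solvated (C-PCM) energy model
#'
#' Rebuilds the cavity at every geometry (fixed polyhedron frame when
#' `frame` is given) and runs the fully coupled PCM-SCF.
#'
#' @param params parameter set.
#' @param solvent a [solvent_model()].
#' @param n_per_sphere tesserae per sphere.
#' @param options SCF options.
#' @param radii_table,scale,hydrogen_spheres cavity options.
#' @param frame optional fixed tessellation frame.
#' @param solver ASC solver selection.
#' @return model object with an `evaluate(mol, P0)` closure.
#' @export
model_pcm <- function(params, solvent = solvent_model(), n_per_sphere = 60,
                      options = scf_options(), radii_table = BONDI_RADII,
                      scale = 1.2, hydrogen_spheres = TRUE, frame = NULL,
                      solver = "auto") {
  structure(list(
    kind = "pcm",
    params = params,
    solvent = solvent,
    n_per_sphere = n_per_sphere,
    evaluate = function(mol, P0 = NULL, need_gradient = TRUE) {
      pcm <- pcm_context(mol, solvent, n_per_sphere = n_per_sphere,
                         radii_table = radii_table, scale = scale,
                         hydrogen_spheres = hydrogen_spheres, frame = frame,
                         solver = solver)
      st <- scf(mol, params, options, pcm = pcm, P0 = P0)
      if (!st$converged) {
        return(list(ok = FALSE, state = st, pcm = pcm))
      }
      g <- NULL
      flagged <- FALSE
      if (need_gradient) {
        tg <- total_gradient(mol, params, st, pcm)
        g <- tg$gradient
        flagged <- any(tg$flagged)
      }
      list(ok = TRUE, energy = st$total_energy, gradient = g, state = st,
           pcm = pcm, flagged = flagged)
    }
  ), class = "sepcm_model")
}
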