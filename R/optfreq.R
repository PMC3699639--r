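#' Geometry optimization (Cartesian BFGS)
#'
#' Quasi-Newton minimization with a unit initial inverse Hessian, a trust cap
#' on the step length and simple backtracking. Convergence when the largest
#' gradient component drops below `threshold`. A line search collapsing to a
#' zero step twice in a row sets the stall flag and terminates (the final
#' geometry is still returned and usable, e.g. for a Hessian).
#'
#' @param mol starting geometry.
#' @param model a [model_gas()] or [model_pcm()].
#' @param threshold convergence threshold on the max gradient component
#'   (hartree/bohr); default 5e-4.
#' @param max_steps maximum optimization steps (default 100).
#' @param max_step_length trust cap on the displacement per step, bohr.
#' @param hessian_update update the BFGS inverse Hessian (set FALSE to mirror
#'   the skip-update workaround for stalling small systems).
#' @param uphill_tol energy increase tolerated when accepting a step (eV).
#'   The default depends on the model: essentially zero in the gas phase
#'   (smooth surface), 0.01 eV with PCM, where tessera appearance/removal
#'   events put walls of a few hundredths of a kcal/mol on the energy
#'   surface that a strict descent condition cannot cross. Convergence is
#'   judged on the gradient, and the lowest-energy geometry seen is returned.
#' @param trajectory_file optional multi-frame XYZ file to append geometries.
#' @return `sepcm_opt` object: final molecule and SCF state, step count,
#'   convergence and stall flags, and a trajectory table.
#' @export
optimize_geometry <- function(mol, model, threshold = 5e-4, max_steps = 100,
                              max_step_length = 0.3, hessian_update = TRUE,
                              uphill_tol = NULL, trajectory_file = NULL) {
  if (is.null(uphill_tol)) {
    uphill_tol <- if (identical(model$kind, "pcm")) 1e-2 else 1e-7
  }
  n <- length(mol$symbols)
  x <- as.numeric(coords_bohr(mol))      # 3n vector, bohr (column-major: xyz per atom)
  ev <- model$evaluate(mol, NULL)
  if (!ev$ok) stop("initial SCF did not converge")
  P <- ev$state$P
  g <- as.numeric(t(ev$gradient))        # matches x layout
  E <- ev$energy
  Hinv <- diag(3 * n)
  traj <- data.frame(step = 0, energy_ev = E, max_grad = max(abs(g)))
  stall <- FALSE
  converged <- max(abs(g)) < threshold
  zero_steps <- 0
  nstep <- 0
  last <- ev
  best <- list(E = E, x = x, ev = ev, g = g)

  while (!converged && !stall && nstep < max_steps) {
    nstep <- nstep + 1
    s <- -as.numeric(Hinv %*% g)
    smax <- max(abs(s))
    if (smax > max_step_length) s <- s * (max_step_length / smax)
    # backtracking on the energy; if no strictly downhill step exists (the
    # moving tessellation makes the energy piecewise smooth, with small walls
    # at tessera appearance/removal events), the best candidate within
    # uphill_tol is taken instead
    lambda <- 1
    accepted <- FALSE
    for (bt in 1:6) {
      xn <- x + lambda * s
      mn <- with_coords_bohr(mol, matrix(xn, 3, n))
      evn <- tryCatch(suppressWarnings(model$evaluate(mn, P)),
                      error = function(e) NULL)
      if (!is.null(evn) && isTRUE(evn$ok) &&
          isTRUE(evn$energy < E + uphill_tol)) {
        accepted <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!accepted) {
      zero_steps <- zero_steps + 1
      if (zero_steps >= 2) { stall <- TRUE; break }
      Hinv <- diag(3 * n)    # reset curvature and retry with steepest descent
      next
    }
    zero_steps <- 0
    gn <- as.numeric(t(evn$gradient))
    if (hessian_update) {
      sv <- lambda * s
      yv <- gn - g
      sy <- sum(sv * yv)
      if (sy > 1e-12) {
        rho <- 1 / sy
        I <- diag(3 * n)
        V <- I - rho * (sv %o% yv)
        Hinv <- V %*% Hinv %*% t(V) + rho * (sv %o% sv)
      }
    }
    x <- x + lambda * s
    mol <- with_coords_bohr(mol, matrix(x, 3, n))
    E <- evn$energy
    g <- gn
    P <- evn$state$P
    last <- evn
    if (E < best$E) best <- list(E = E, x = x, ev = evn, g = g)
    traj <- rbind(traj, data.frame(step = nstep, energy_ev = E,
                                   max_grad = max(abs(g))))
    if (!is.null(trajectory_file)) {
      append_xyz(mol, trajectory_file,
                 comment = sprintf("step %d E = %.8f eV", nstep, E))
    }
    converged <- max(abs(g)) < threshold
  }

  # report the lowest-energy point visited unless the walk ended lower
  if (best$E < E - 1e-12 && !converged) {
    x <- best$x; E <- best$E; g <- best$g; last <- best$ev
    mol <- with_coords_bohr(mol, matrix(x, 3, n))
  }
  structure(list(molecule = mol, state = last$state, pcm = last$pcm,
                 energy = E, max_grad = max(abs(g)), steps = nstep,
                 converged = converged, stalled = stall,
                 trajectory = traj), class = "sepcm_opt")
}

#' @export
print.sepcm_opt <- function(x, ...) {
  cat("<sepcm_opt>",
      if (x$converged) "converged" else if (x$stalled) "STALLED" else "max steps",
      "after", x$steps, "steps; max |g| =", signif(x$max_grad, 3),
      "au/bohr\n")
  invisible(x)
}

#' Double-difference Hessian
#'
#' Central differences of the gradient, one displacement pair per Cartesian
#' component, then symmetrized.
#'
#' @param mol geometry (ideally a stationary point).
#' @param model energy model (its gradient is differentiated).
#' @param step displacement, bohr (default 0.01).
#' @return list with the symmetric `hessian` (hartree/bohr^2, 3n x 3n) and
#'   the pre-symmetrization asymmetry `asym`.
#' @export
hessian_double_difference <- function(mol, model, step = 0.01) {
  n <- length(mol$symbols)
  cb <- coords_bohr(mol)
  ev0 <- model$evaluate(mol, NULL, need_gradient = FALSE)
  if (!ev0$ok) stop("SCF did not converge at the reference geometry")
  P <- ev0$state$P
  H <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) {
    for (c in 1:3) {
      k <- 3 * (a - 1) + c
      cp <- cb; cp[c, a] <- cp[c, a] + step
      cm <- cb; cm[c, a] <- cm[c, a] - step
      evp <- model$evaluate(with_coords_bohr(mol, cp), P)
      evm <- model$evaluate(with_coords_bohr(mol, cm), P)
      if (!evp$ok || !evm$ok) {
        stop("SCF failed at Hessian displacement (atom ", a, ", coord ", c, ")")
      }
      H[, k] <- (as.numeric(t(evp$gradient)) - as.numeric(t(evm$gradient))) /
        (2 * step)
    }
  }
  asym <- max(abs(H - t(H)))
  list(hessian = (H + t(H)) / 2, asym = asym)
}

#' Harmonic vibrational frequencies
#'
#' Mass-weights the Hessian, projects out the rigid-body translations and
#' rotations (5 for linear geometries), diagonalizes and converts to
#' wavenumbers. Negative eigenvalues are reported as negative frequencies
#' (imaginary modes).
#'
#' @param hessian Cartesian Hessian, hartree/bohr^2.
#' @param mol molecule (masses and geometry).
#' @return `sepcm_freq` object: sorted `frequencies` (cm^-1, imaginary as
#'   negative), `imaginary_count`, `modes` (mass-weighted), and the rigid-mode
#'   magnitudes before removal.
#' @export
frequencies <- function(hessian, mol) {
  n <- length(mol$symbols)
  if (n == 1) {
    return(structure(list(frequencies = numeric(0), imaginary_count = 0L,
                          modes = matrix(0, 3, 0), rigid = numeric(0)),
                     class = "sepcm_freq"))
  }
  m_amu <- ATOMIC_MASSES[mol$symbols]
  m_au <- rep(m_amu, each = 3) / AMU_PER_ELECTRON_MASS  # amu -> m_e
  Hm <- hessian / sqrt(outer(m_au, m_au))
  # rigid-body basis in mass-weighted coordinates
  x <- coords_bohr(mol)                  # 3 x n
  com <- as.numeric(x %*% (m_amu / sum(m_amu)))
  xc <- sweep(x, 1, com)
  B <- matrix(0, 3 * n, 6)
  sm <- sqrt(rep(m_amu, each = 3))
  for (c in 1:3) B[seq(c, 3 * n, by = 3), c] <- 1
  for (a in seq_len(n)) {
    r <- xc[, a]
    B[3 * (a - 1) + (1:3), 4] <- c(0, -r[3], r[2])
    B[3 * (a - 1) + (1:3), 5] <- c(r[3], 0, -r[1])
    B[3 * (a - 1) + (1:3), 6] <- c(-r[2], r[1], 0)
  }
  B <- B * sm
  qrB <- qr(B)
  nr <- qrB$rank                          # 5 for linear molecules
  Q <- qr.Q(qrB)[, seq_len(nr), drop = FALSE]
  rigid <- vapply(seq_len(nr), function(k) {
    v <- Q[, k]
    sqrt(abs(sum(v * (Hm %*% v)))) * WAVENUMBER_PER_AU
  }, 0)
  Pproj <- diag(3 * n) - Q %*% t(Q)
  Hp <- Pproj %*% Hm %*% Pproj
  ee <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE)
  lam <- ee$values
  ord <- order(abs(lam))
  drop_idx <- ord[seq_len(nr)]
  keep <- setdiff(seq_along(lam), drop_idx)
  lam_v <- lam[keep]
  nu <- sign(lam_v) * sqrt(abs(lam_v)) * WAVENUMBER_PER_AU
  o <- order(nu)
  structure(list(frequencies = nu[o],
                 imaginary_count = sum(nu < 0),
                 modes = ee$vectors[, keep, drop = FALSE][, o, drop = FALSE],
                 rigid = rigid),
            class = "sepcm_freq")
}

#' @export
print.sepcm_freq <- function(x, ...) {
  cat("<sepcm_freq>", length(x$frequencies), "vibrational modes;",
      x$imaginary_count, "imaginary\n")
  if (length(x$frequencies) > 0) {
    cat(" ", paste(sprintf("%.1f", x$frequencies), collapse = " "), "cm^-1\n")
  }
  invisible(x)
}

#' Mean absolute deviation between two frequency sets
#'
#' Sorts both sets ascending and pairs by index. Imaginary modes are excluded
#' (with their counts attached); a count mismatch after exclusion is an error
#' that the caller must resolve.
#'
#' @param solvated,gas `sepcm_freq` objects (or numeric vectors, cm^-1).
#' @return MAD in cm^-1 with attributes `n_modes`,
#'   `imaginary_solvated`, `imaginary_gas`.
#' @export
mad_frequencies <- function(solvated, gas) {
  fs <- if (inherits(solvated, "sepcm_freq")) solvated$frequencies else solvated
  fg <- if (inherits(gas, "sepcm_freq")) gas$frequencies else gas
  is_ <- sum(fs < 0); ig <- sum(fg < 0)
  fs <- sort(fs[fs >= 0])
  fg <- sort(fg[fg >= 0])
  if (length(fs) != length(fg)) {
    stop("vibrational mode counts differ after excluding imaginary modes (",
         length(fs), " vs ", length(fg), ")")
  }
  mad <- if (length(fs) == 0) 0 else mean(abs(fs - fg))
  structure(mad, n_modes = length(fs), imaginary_solvated = is_,
            imaginary_gas = ig)
}
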