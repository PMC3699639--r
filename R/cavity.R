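#' Assign cavity spheres to atoms
#'
#' One sphere per atom with radius `table value x scale`. The default table is
#' the Bondi van der Waals set and the default scale 1.2, the common PCM
#' convention; both are exposed because the cavity radii are the dominant
#' uncertainty when comparing solvation free energies across codes.
#'
#' @param mol a [molecule()].
#' @param radii_table named numeric vector of base radii (Angstrom).
#' @param scale dimensionless scale factor (> 0).
#' @param hydrogen_spheres include spheres on hydrogens (default TRUE).
#' @return data frame with atom index, element, center (Angstrom) and radius
#'   (Angstrom).
#' @export
assign_radii <- function(mol, radii_table = BONDI_RADII, scale = 1.2,
                         hydrogen_spheres = TRUE) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  miss <- setdiff(unique(mol$symbols), names(radii_table))
  if (length(miss) > 0) {
    stop("radii table lacks element(s): ", paste(miss, collapse = ", "))
  }
  keep <- if (hydrogen_spheres) rep(TRUE, length(mol$symbols)) else mol$symbols != "H"
  data.frame(
    atom = seq_along(mol$symbols)[keep],
    element = mol$symbols[keep],
    x = mol$coords[keep, 1], y = mol$coords[keep, 2], z = mol$coords[keep, 3],
    radius = unname(radii_table[mol$symbols[keep]] * scale)
  )
}

# deterministic molecule-bound frame for seeding the tessellation polyhedron:
# principal axes of index-weighted coordinates. The small index weighting
# breaks the axis degeneracy of symmetric tops deterministically, so the frame
# (and with it every tessera) co-rotates exactly with the molecule.
principal_frame <- function(mol) {
  x <- mol$coords
  n <- nrow(x)
  if (n == 1) return(diag(3))
  w <- ATOMIC_MASSES[mol$symbols] * (1 + 0.001 * seq_len(n))
  ctr <- colSums(x * w) / sum(w)
  xc <- sweep(x, 2, ctr)
  M <- crossprod(xc * sqrt(w))
  ev <- eigen(M, symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:3) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' GEPOL tessellation of the solute cavity
#'
#' Builds the van der Waals cavity from interlocked atomic spheres and
#' tessellates each sphere with 60 x 4^k triangles from a subdivided pentakis
#' dodecahedron. Tesserae whose representative point falls inside another
#' sphere are removed; partially exposed tesserae get their area from the
#' Gauss-Bonnet theorem applied to the clipped spherical polygon. The
#' polyhedron is seeded in the molecule's principal-axis frame so the
#' tessellation co-rotates rigidly with the solute.
#'
#' @param mol a [molecule()].
#' @param n_per_sphere 60, 240 or 960 initial tesserae per sphere.
#' @param radii_table,scale,hydrogen_spheres see [assign_radii()].
#' @param frame optional 3 x 3 rotation seeding the polyhedron (defaults to
#'   the principal-axis frame); pass an explicit frame to keep the
#'   tessellation fixed across finite-difference displacements.
#' @return object of class `sepcm_cavity` with tessera positions (bohr),
#'   exposed areas (bohr^2), outward normals, parent sphere indices and the
#'   sphere list.
#' @export
tessellate_gepol <- function(mol, n_per_sphere = 60, radii_table = BONDI_RADII,
                             scale = 1.2, hydrogen_spheres = TRUE, frame = NULL) {
  if (!n_per_sphere %in% c(60, 240, 960)) {
    stop("n_per_sphere must be one of 60, 240, 960")
  }
  sph <- assign_radii(mol, radii_table, scale, hydrogen_spheres)
  if (is.null(frame)) frame <- principal_frame(mol)
  centers <- t(angstrom_to_bohr(as.matrix(sph[, c("x", "y", "z")])))
  radii <- angstrom_to_bohr(sph$radius)
  res <- cpp_tessellate(centers, radii, as.integer(n_per_sphere), frame)
  sphere_atom <- sph$atom[res$sphere]
  pos <- t(res$pos)
  nrm <- (pos - t(centers)[res$sphere, , drop = FALSE]) / radii[res$sphere]
  structure(list(
    pos_bohr = pos,
    area_bohr2 = as.numeric(res$area),
    normal = nrm,
    sphere = as.integer(sphere_atom),     # owning atom index
    sphere_row = as.integer(res$sphere),  # row in the sphere table
    tri = as.integer(res$tri),
    total_area = res$total_area,
    spheres = sph,
    centers_bohr = t(centers),
    radii_bohr = radii,
    n_per_sphere = as.integer(n_per_sphere),
    frame = frame,
    radii_table = radii_table,
    scale = scale,
    hydrogen_spheres = hydrogen_spheres,
    scheme = "gepol-gb"
  ), class = "sepcm_cavity")
}

#' @export
print.sepcm_cavity <- function(x, ...) {
  cat("<sepcm_cavity>", length(x$area_bohr2), "tesserae on",
      nrow(x$spheres), "spheres (", x$n_per_sphere, "per sphere );",
      sprintf("total area %.3f bohr^2\n", x$total_area))
  invisible(x)
}

#' Rebuild a cavity for a displaced geometry
#'
#' Deterministic rebuild with the tessellation settings and polyhedron frame
#' of an existing cavity, so tesserae of identical inputs come back in
#' bit-identical order and can be matched across finite-difference
#' displacements via their (sphere, triangle) keys.
#'
#' @param cavity an existing `sepcm_cavity`.
#' @param mol_displaced molecule with the same atoms at displaced positions.
#' @return a new `sepcm_cavity`.
#' @export
cavity_displacement_rebuild <- function(cavity, mol_displaced) {
  if (length(mol_displaced$symbols) != length(unique(cavity$spheres$atom)) &&
      cavity$hydrogen_spheres) {
    stop("displaced molecule has a different atom count")
  }
  tessellate_gepol(mol_displaced, n_per_sphere = cavity$n_per_sphere,
                   radii_table = cavity$radii_table, scale = cavity$scale,
                   hydrogen_spheres = cavity$hydrogen_spheres,
                   frame = cavity$frame)
}

#' Dump a cavity to CSV (index, sphere, position, area)
#' @param cavity a `sepcm_cavity`.
#' @param path output file.
#' @export
write_cavity_csv <- function(cavity, path) {
  df <- data.frame(index = seq_along(cavity$area_bohr2),
                   sphere = cavity$sphere,
                   x = cavity$pos_bohr[, 1], y = cavity$pos_bohr[, 2],
                   z = cavity$pos_bohr[, 3], area = cavity$area_bohr2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
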