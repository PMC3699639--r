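#' Construct a molecule
#'
#' @param symbols character vector of element symbols (H, C, N, O).
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @param charge integer net charge.
#' @param multiplicity spin multiplicity; only closed-shell singlets (1) are
#'   supported.
#' @return object of class `sepcm_molecule`.
#' @export
molecule <- function(symbols, coords, charge = 0, multiplicity = 1) {
  symbols <- as.character(symbols)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3 || nrow(coords) != length(symbols)) {
    stop("coords must be an n x 3 matrix matching length(symbols)")
  }
  if (multiplicity != 1) stop("only restricted closed-shell (multiplicity 1) is supported")
  bad <- setdiff(unique(symbols), SUPPORTED_ELEMENTS)
  if (length(bad) > 0) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  mol <- structure(list(symbols = symbols, coords = coords,
                        charge = as.integer(charge), multiplicity = 1L),
                   class = "sepcm_molecule")
  if (n_electrons(mol) %% 2 != 0) {
    stop("odd electron count (", n_electrons(mol), "); closed shell required")
  }
  mol
}

valence_electrons <- c(H = 1, C = 4, N = 5, O = 6)

#' Number of valence electrons of a molecule
#' @param mol a `sepcm_molecule`.
#' @return integer electron count (valence electrons minus net charge).
#' @export
n_electrons <- function(mol) {
  sum(valence_electrons[mol$symbols]) - mol$charge
}

#' @export
print.sepcm_molecule <- function(x, ...) {
  cat("<sepcm_molecule>", length(x$symbols), "atoms, charge", x$charge, "\n")
  invisible(x)
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: atom count, comment, then `symbol x y z` in Angstrom.
#' A `charge=N` token in the comment line sets the net charge.
#'
#' @param path file path.
#' @return a [molecule()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  comment <- if (length(lines) >= 2) lines[2] else ""
  charge <- 0L
  m <- regmatches(comment, regexpr("charge=-?[0-9]+", comment))
  if (length(m) == 1) charge <- as.integer(sub("charge=", "", m))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  symbols <- vapply(rows, `[`, "", 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  molecule(symbols, coords, charge = charge)
}

#' Write a molecule to an XYZ file
#' @param mol a [molecule()].
#' @param path output file.
#' @param comment extra comment text (the net charge is always recorded).
#' @export
write_xyz <- function(mol, path, comment = "") {
  n <- length(mol$symbols)
  lines <- c(
    as.character(n),
    trimws(paste0("charge=", mol$charge, " ", comment)),
    sprintf("%-2s %16.10f %16.10f %16.10f", mol$symbols,
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Append a geometry to a multi-frame XYZ trajectory file
#' @inheritParams write_xyz
#' @export
append_xyz <- function(mol, path, comment = "") {
  n <- length(mol$symbols)
  lines <- c(
    as.character(n),
    trimws(paste0("charge=", mol$charge, " ", comment)),
    sprintf("%-2s %16.10f %16.10f %16.10f", mol$symbols,
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  )
  cat(paste(lines, collapse = "\n"), "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}

#' Read coordinates from a PDB file
#'
#' Minimal reader for demo-scale single points: ATOM/HETATM records,
#' coordinates and the element column only. No protonation or connectivity
#' logic.
#'
#' @param path PDB file.
#' @param charge net charge to assign.
#' @return a [molecule()].
#' @export
read_pdb <- function(path, charge = 0) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(lines) == 0) stop("no ATOM/HETATM records in ", path)
  xyz <- cbind(as.numeric(substr(lines, 31, 38)),
               as.numeric(substr(lines, 39, 46)),
               as.numeric(substr(lines, 47, 54)))
  el <- trimws(substr(lines, 77, 78))
  fallback <- toupper(substr(trimws(substr(lines, 13, 16)), 1, 1))
  el <- ifelse(nzchar(el), el, fallback)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 10)))
  molecule(el, xyz, charge = charge)
}

# coordinates as 3 x n matrix in bohr (C++ calling convention)
coords_bohr <- function(mol) t(angstrom_to_bohr(mol$coords))

with_coords_bohr <- function(mol, cb) {
  mol$coords <- bohr_to_angstrom(t(cb))
  mol
}
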