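#' Read a V2000 connection-table (MOL/SDF) molecule
#'
#' Parses the header counts line, the atom block (coordinates and element)
#' and the bond block of a single V2000 connection table. Aromatic bonds
#' (type 4) are kept as order 4; ring membership is perceived from the bond
#' graph. Only the first structure of an SD file is read.
#'
#' @param path file path, or a character vector of lines.
#' @return a \linkS4class{Molecule}.
#' @export
readMolFile <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) &&
               file.exists(path)) readLines(path)
           else if (length(path) == 1L) strsplit(path, "\n")[[1]]
           else path
  if (length(lines) < 4L) stop("MOL parse error: file too short")
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1L)
    stop("MOL parse error at line 4: malformed counts line")
  if (length(lines) < 4L + na + nb)
    stop("MOL parse error: truncated atom/bond block")
  atom_lines <- lines[4L + seq_len(na)]
  atoms <- data.frame(
    element = trimws(substr(atom_lines, 32, 34)),
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30)))
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z))
    stop("MOL parse error: malformed atom block")
  bonds <- NULL
  if (nb > 0L) {
    bond_lines <- lines[4L + na + seq_len(nb)]
    bonds <- data.frame(
      a = as.integer(substr(bond_lines, 1, 3)),
      b = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9)))
    if (anyNA(bonds$a) || anyNA(bonds$b) || anyNA(bonds$order))
      stop("MOL parse error: malformed bond block")
  }
  Molecule(atoms, bonds)
}

#' Read a molecule from PDB-style coordinate records
#'
#' Reads \code{HETATM} (and optionally \code{ATOM}) records. PDB files
#' carry no bond block, so bonds are perceived by distance: two atoms are
#' bonded when their separation is below \code{tolerance} times the sum of
#' their covalent radii. All perceived bonds are single; ring flags come
#' from the perceived graph. Suited to the small-molecule (ligand) records
#' this package needs, not to whole proteins.
#'
#' @param path file path or character vector of lines.
#' @param hetatmOnly read only \code{HETATM} records (default) or also
#'   \code{ATOM}.
#' @param tolerance multiplier on the covalent-radius sum (default 1.3).
#' @return a \linkS4class{Molecule}.
#' @export
readPdbMolecule <- function(path, hetatmOnly = TRUE, tolerance = 1.3) {
  lines <- if (length(path) == 1L && !grepl("\n", path) &&
               file.exists(path)) readLines(path)
           else if (length(path) == 1L) strsplit(path, "\n")[[1]]
           else path
  keep <- startsWith(lines, "HETATM")
  if (!hetatmOnly) keep <- keep | startsWith(lines, "ATOM")
  rec <- lines[keep]
  if (length(rec) == 0L) stop("PDB parse error: no coordinate records")
  element <- trimws(substr(rec, 77, 78))
  # fall back to the first letter of the atom name when col 77-78 is blank
  blank <- !nzchar(element)
  element[blank] <- gsub("[^A-Za-z].*$", "",
                         trimws(substr(rec[blank], 13, 16)))
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  atoms <- data.frame(element = element,
                      x = as.numeric(substr(rec, 31, 38)),
                      y = as.numeric(substr(rec, 39, 46)),
                      z = as.numeric(substr(rec, 47, 54)))
  if (anyNA(atoms$x)) stop("PDB parse error: malformed coordinates")
  bonds <- .perceiveBonds(atoms, tolerance)
  Molecule(atoms, bonds)
}

.covalentRadius <- function(element) {
  tab <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
           S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)
  r <- unname(tab[element])
  r[is.na(r)] <- tab[["C"]]
  r
}

.perceiveBonds <- function(atoms, tolerance) {
  n <- nrow(atoms)
  if (n < 2L) return(NULL)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rc <- .covalentRadius(atoms$element)
  d <- as.matrix(stats::dist(xyz))
  cutoff <- outer(rc, rc, "+") * tolerance
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) == 0L) return(NULL)
  data.frame(a = hit[, 1], b = hit[, 2], order = 1L)
}
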