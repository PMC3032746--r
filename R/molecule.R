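#' Construct a Molecule from atom and bond tables
#'
#' @param atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z} (Angstrom) and optionally \code{radius}; missing radii are
#'   filled from the Bondi van der Waals set via [vdwRadius()].
#' @param bonds data.frame with columns \code{a}, \code{b}, \code{order}
#'   (1, 2, 3, or 4 for aromatic) and optionally \code{in_ring}; missing
#'   ring flags are computed from the bond graph via [perceiveRings()].
#' @return a validated \linkS4class{Molecule}.
#' @examples
#' Molecule(data.frame(element = "C", x = 0, y = 0, z = 0))
#' @export
Molecule <- function(atoms, bonds = NULL) {
  atoms$element <- as.character(atoms$element)
  if (is.null(atoms$radius))
    atoms$radius <- vdwRadius(atoms$element)
  if (is.null(bonds) || nrow(bonds) == 0L)
    bonds <- data.frame(a = integer(), b = integer(), order = integer(),
                        in_ring = logical())
  bonds$a <- as.integer(bonds$a); bonds$b <- as.integer(bonds$b)
  bonds$order <- as.integer(bonds$order)
  if (is.null(bonds$in_ring)) {
    ok <- nrow(bonds) == 0L ||
      all(bonds$a >= 1L & bonds$a <= nrow(atoms) &
          bonds$b >= 1L & bonds$b <= nrow(atoms) & bonds$a != bonds$b)
    # leave flags FALSE on malformed graphs; validity reports the defect
    bonds$in_ring <- if (ok) perceiveRings(nrow(atoms), bonds)
                     else FALSE
  }
  new("Molecule", atoms = atoms[, c("element", "x", "y", "z", "radius")],
      bonds = bonds[, c("a", "b", "order", "in_ring")])
}

#' Bondi van der Waals radii
#'
#' @param element character vector of element symbols.
#' @param overrides optional named numeric of per-element replacements.
#' @return radii in Angstrom; elements outside the tabulated set fall back
#'   to the carbon radius (1.70 A).
#' @examples
#' vdwRadius(c("C", "N", "O", "H"))
#' @export
vdwRadius <- function(element, overrides = NULL) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
           S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)
  if (!is.null(overrides)) tab[names(overrides)] <- overrides
  r <- unname(tab[element])
  r[is.na(r)] <- tab[["C"]]
  r
}

#' Flag ring bonds in a bond graph
#'
#' A bond is in a ring exactly when removing it leaves its two endpoints
#' connected. Determined by breadth-first search per bond; molecules here
#' are small enough that no smallest-set-of-smallest-rings machinery is
#' warranted.
#'
#' @param nAtoms number of atoms.
#' @param bonds data.frame with columns \code{a}, \code{b}.
#' @return logical vector, one flag per bond row.
#' @export
perceiveRings <- function(nAtoms, bonds) {
  nb <- nrow(bonds)
  if (nb == 0L) return(logical(0))
  adj <- vector("list", nAtoms)
  for (k in seq_len(nb)) {
    adj[[bonds$a[k]]] <- c(adj[[bonds$a[k]]], k)
    adj[[bonds$b[k]]] <- c(adj[[bonds$b[k]]], k)
  }
  other <- function(k, v) if (bonds$a[k] == v) bonds$b[k] else bonds$a[k]
  vapply(seq_len(nb), function(k) {
    src <- bonds$a[k]; dst <- bonds$b[k]
    seen <- logical(nAtoms); seen[src] <- TRUE
    queue <- src
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- other(e, v)
        if (!seen[w]) {
          if (w == dst) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

#' Generate toy molecules with known geometry and topology
#'
#' Fixture factory for the geometric descriptors. Four shapes are
#' available, each with documented reference properties:
#' \describe{
#'   \item{\code{single_atom}}{one atom of radius \code{radius}; its SASA is
#'     exactly \eqn{4\pi(r + probe)^2}.}
#'   \item{\code{dimer}}{two \code{radius}-spheres \code{separation} apart
#'     along x; at separations beyond \eqn{2(r + probe)} the SASA is exactly
#'     additive.}
#'   \item{\code{linear_alkane}}{an n-carbon chain (1.54 A C-C bonds, ideal
#'     tetrahedral zigzag); it has \eqn{\max(n - 3, 0)} rotatable bonds
#'     under the package's definition.}
#'   \item{\code{ring}}{an n-membered aromatic carbocycle (regular polygon,
#'     1.40 A sides); all bonds are ring bonds, so 0 rotatable bonds.}
#' }
#'
#' @param kind which shape to build.
#' @param n number of atoms for \code{linear_alkane} (>= 1) and \code{ring}
#'   (>= 3).
#' @param separation centre-centre distance for \code{dimer}, Angstrom.
#' @param radius van der Waals radius for \code{single_atom} / \code{dimer}.
#' @return a \linkS4class{Molecule}.
#' @examples
#' rotatableBondCount(makeSyntheticMolecule("linear_alkane", n = 6))  # 3
#' @export
makeSyntheticMolecule <- function(kind = c("linear_alkane", "ring", "dimer",
                                           "single_atom"),
                                  n = 6L, separation = 10, radius = 1.9) {
  kind <- match.arg(kind)
  switch(kind,
    single_atom = Molecule(
      data.frame(element = "C", x = 0, y = 0, z = 0, radius = radius)),
    dimer = {
      if (separation < 0) stop("separation must be >= 0")
      Molecule(data.frame(element = c("C", "C"),
                          x = c(0, separation), y = 0, z = 0,
                          radius = radius))
    },
    linear_alkane = {
      if (n < 1L) stop("n must be >= 1")
      i <- seq_len(n)
      # tetrahedral zigzag in the xy plane, C-C 1.54 A
      half <- 1.54 * sin(109.47 / 2 * pi / 180)
      rise <- 1.54 * cos(109.47 / 2 * pi / 180)
      atoms <- data.frame(element = "C",
                          x = (i - 1) * half,
                          y = ifelse(i %% 2 == 0, rise, 0),
                          z = 0)
      bonds <- if (n >= 2L)
        data.frame(a = seq_len(n - 1L), b = 2:n, order = 1L,
                   in_ring = FALSE)
      else NULL
      Molecule(atoms, bonds)
    },
    ring = {
      if (n < 3L) stop("ring needs n >= 3")
      side <- 1.40
      rad <- side / (2 * sin(pi / n))
      th <- 2 * pi * (seq_len(n) - 1) / n
      atoms <- data.frame(element = "C", x = rad * cos(th),
                          y = rad * sin(th), z = 0)
      bonds <- data.frame(a = seq_len(n), b = c(2:n, 1L), order = 4L,
                          in_ring = TRUE)
      Molecule(atoms, bonds)
    })
}
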