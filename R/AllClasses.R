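#' @import methods
NULL

#' FmoSystem: a fragmented molecular system with pair interaction energies
#'
#' Container for the parsed result of a fragment molecular orbital (FMO)
#' calculation: one row per fragment (monomer) with its self-consistent-field
#' energy, and one row per computed fragment pair (dimer) carrying the pair
#' interaction energy (PIE, also called the inter-fragment interaction energy,
#' IFIE) and, when available, the dimer energy and the four energy
#' decomposition components (electrostatics ES, exchange repulsion EX,
#' charge transfer + mixed terms CT, dispersion DI).
#'
#' @slot fragments data.frame with columns \code{index} (1-based, contiguous),
#'   \code{label} (residue or ligand name) and \code{energy} (Hartree).
#' @slot pairs data.frame with columns \code{i}, \code{j} (fragment indices,
#'   \code{i < j}), \code{dimer_energy} (Hartree, may be \code{NA}),
#'   \code{pie} (kcal/mol) and component columns \code{es}, \code{ex},
#'   \code{ct}, \code{di} (kcal/mol, may be \code{NA}).
#' @slot ligandIndex integer; index of the ligand fragment, or \code{NA} when
#'   no ligand has been designated.
#'
#' @seealso [parseFmoOutput()], [pieSum()], [totalEnergy()], [ifieMap()]
#' @export
setClass("FmoSystem",
  representation(
    fragments   = "data.frame",
    pairs       = "data.frame",
    ligandIndex = "integer"
  ),
  prototype(
    fragments = data.frame(index = integer(), label = character(),
                           energy = numeric()),
    pairs = data.frame(i = integer(), j = integer(),
                       dimer_energy = numeric(), pie = numeric(),
                       es = numeric(), ex = numeric(), ct = numeric(),
                       di = numeric()),
    ligandIndex = NA_integer_
  )
)

setValidity("FmoSystem", function(object) {
  fr <- object@fragments
  pr <- object@pairs
  msgs <- character()
  need_fr <- c("index", "label", "energy")
  if (!all(need_fr %in% names(fr)))
    return("fragments must have columns index, label, energy")
  need_pr <- c("i", "j", "pie")
  if (!all(need_pr %in% names(pr)))
    return("pairs must have columns i, j, pie")
  n <- nrow(fr)
  if (n > 0 && !identical(as.integer(fr$index), seq_len(n)))
    msgs <- c(msgs, "fragment indices must be contiguous 1..N")
  if (nrow(pr) > 0) {
    if (any(pr$i >= pr$j))
      msgs <- c(msgs, "pairs must satisfy i < j")
    if (any(pr$i < 1L | pr$j > n))
      msgs <- c(msgs, "pair references a non-existent fragment")
    if (anyDuplicated(paste(pr$i, pr$j)))
      msgs <- c(msgs, "duplicate fragment pair")
  }
  li <- object@ligandIndex
  if (length(li) != 1L)
    msgs <- c(msgs, "ligandIndex must have length 1")
  else if (!is.na(li) && (li < 1L || li > n))
    msgs <- c(msgs, "ligandIndex out of range")
  if (length(msgs) == 0) TRUE else msgs
})

#' Molecule: atoms, coordinates, radii and bonds
#'
#' Minimal small-molecule container for the geometric descriptor
#' calculations: solvent accessible surface area needs per-atom coordinates
#' and van der Waals radii; rotatable-bond counting needs the heavy-atom
#' bond graph with bond orders and ring membership.
#'
#' @slot atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z} (Angstrom) and \code{radius} (van der Waals radius, Angstrom,
#'   strictly positive).
#' @slot bonds data.frame with columns \code{a}, \code{b} (atom indices),
#'   \code{order} (1, 2, 3, or 4 for aromatic) and \code{in_ring} (logical).
#'
#' @seealso [readMolFile()], [readPdbMolecule()], [shrakeRupleySasa()],
#'   [rotatableBondCount()]
#' @export
setClass("Molecule",
  representation(atoms = "data.frame", bonds = "data.frame"),
  prototype(
    atoms = data.frame(element = character(), x = numeric(), y = numeric(),
                       z = numeric(), radius = numeric()),
    bonds = data.frame(a = integer(), b = integer(), order = integer(),
                       in_ring = logical())
  )
)

setValidity("Molecule", function(object) {
  at <- object@atoms
  bd <- object@bonds
  if (!all(c("element", "x", "y", "z", "radius") %in% names(at)))
    return("atoms must have columns element, x, y, z, radius")
  if (!all(c("a", "b", "order", "in_ring") %in% names(bd)))
    return("bonds must have columns a, b, order, in_ring")
  msgs <- character()
  if (nrow(at) > 0 && any(!is.finite(at$radius) | at$radius <= 0))
    msgs <- c(msgs, "atom radii must be strictly positive")
  if (nrow(bd) > 0) {
    if (any(bd$a < 1L | bd$a > nrow(at) | bd$b < 1L | bd$b > nrow(at)))
      msgs <- c(msgs, "bond references a non-existent atom")
    if (any(bd$a == bd$b))
      msgs <- c(msgs, "self-bond not allowed")
    key <- paste(pmin(bd$a, bd$b), pmax(bd$a, bd$b))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate bond")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' PlsModel: an autoscaled NIPALS partial least squares regression model
#'
#' Stores everything needed to reproduce and apply a PLS fit: the
#' autoscaling parameters of the descriptor block and the response, the
#' per-component NIPALS weight and loading vectors, and the back-transformed
#' regression coefficients that map raw (unscaled) descriptor rows directly
#' to predictions in the response's original units.
#'
#' @slot nComponents integer, number of latent components A.
#' @slot columns character, descriptor column names in model order.
#' @slot xMeans,xSds numeric, per-column autoscaling parameters.
#' @slot yMean,ySd numeric, response scaling parameters.
#' @slot weights p x A matrix of NIPALS weight vectors (unit norm).
#' @slot xLoadings p x A matrix of X loadings.
#' @slot yLoadings length-A numeric of inner-relation y loadings.
#' @slot scores n x A matrix of training score vectors (mutually orthogonal).
#' @slot coefficients length-p numeric, regression coefficients on the raw
#'   descriptor scale.
#' @slot intercept numeric, intercept on the raw scale.
#' @slot fitted numeric, training-set fitted values.
#'
#' @seealso [fitPls()], [predict,PlsModel-method]
#' @export
setClass("PlsModel",
  representation(
    nComponents  = "integer",
    columns      = "character",
    xMeans       = "numeric",
    xSds         = "numeric",
    yMean        = "numeric",
    ySd          = "numeric",
    weights      = "matrix",
    xLoadings    = "matrix",
    yLoadings    = "numeric",
    scores       = "matrix",
    coefficients = "numeric",
    intercept    = "numeric",
    fitted       = "numeric"
  )
)

setValidity("PlsModel", function(object) {
  A <- object@nComponents
  p <- length(object@columns)
  msgs <- character()
  if (A < 1L) msgs <- c(msgs, "nComponents must be >= 1")
  if (A > p) msgs <- c(msgs, "nComponents exceeds number of descriptor columns")
  if (length(object@xMeans) != p || length(object@xSds) != p)
    msgs <- c(msgs, "scaling parameter length mismatch")
  if (ncol(object@weights) != A || ncol(object@xLoadings) != A ||
      length(object@yLoadings) != A)
    msgs <- c(msgs, "component dimension mismatch")
  if (length(object@coefficients) != p)
    msgs <- c(msgs, "coefficient length mismatch")
  if (length(msgs) == 0) TRUE else msgs
})

setMethod("show", "FmoSystem", function(object) {
  n <- nrow(object@fragments)
  cat("FmoSystem:", n, "fragments,", nrow(object@pairs), "pair interactions\n")
  if (!is.na(object@ligandIndex)) {
    lab <- object@fragments$label[object@ligandIndex]
    cat("  ligand fragment:", object@ligandIndex, paste0("(", lab, ")"), "\n")
    cat("  sum of ligand PIEs:",
        format(pieSum(object, object@ligandIndex), digits = 6), "kcal/mol\n")
  }
  has_comp <- nrow(object@pairs) > 0 && any(!is.na(object@pairs$es))
  cat("  energy decomposition components:",
      if (has_comp) "present" else "absent", "\n")
  invisible(object)
})

setMethod("show", "Molecule", function(object) {
  cat("Molecule:", nrow(object@atoms), "atoms,", nrow(object@bonds), "bonds\n")
  if (nrow(object@atoms) > 0) {
    tab <- table(object@atoms$element)
    cat("  composition:",
        paste0(names(tab), tab, collapse = " "), "\n")
  }
  invisible(object)
})

setMethod("show", "PlsModel", function(object) {
  cat("PlsModel:", object@nComponents, "component(s),",
      length(object@columns), "descriptor(s)\n")
  cat("  columns:", paste(object@columns, collapse = ", "), "\n")
  cat("  coefficients (raw scale):\n")
  print(round(stats::setNames(object@coefficients, object@columns), 4))
  cat("  intercept:", round(object@intercept, 4), "\n")
  invisible(object)
})
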