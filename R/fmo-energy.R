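#' Assemble the FMO total energy from monomer and dimer energies
#'
#' The two-body FMO expansion assembles the total electronic energy of the
#' fragmented system as
#' \deqn{E = \sum_I E_I + \sum_{I>J} (E_{IJ} - E_I - E_J)}
#' where \eqn{E_I} are the monomer SCF energies in the Coulomb field of the
#' remaining fragments and \eqn{E_{IJ}} the dimer energies. Pairs omitted
#' from the log (far-separated dimers in distance-thresholded runs)
#' contribute nothing, which is the non-interacting approximation for them.
#'
#' @param system an \linkS4class{FmoSystem}; every listed pair must carry a
#'   dimer energy.
#' @return total energy, Hartree.
#' @examples
#' gen <- makeSyntheticFmoLog(3, seed = 5)
#' totalEnergy(gen$system)
#' @export
totalEnergy <- function(system) {
  fr <- fmoFragments(system)
  pr <- fmoPairs(system)
  if (nrow(pr) > 0 && anyNA(pr$dimer_energy)) {
    k <- which(is.na(pr$dimer_energy))[1]
    stop("pair (", pr$i[k], ",", pr$j[k], ") has no dimer energy",
         call. = FALSE)
  }
  e <- sum(fr$energy)
  if (nrow(pr) > 0)
    e <- e + sum(pr$dimer_energy - fr$energy[pr$i] - fr$energy[pr$j])
  e
}

#' Sum the pair interaction energies involving one fragment
#'
#' Summing all PIEs between the ligand fragment and the receptor fragments
#' estimates the gas-phase binding enthalpy of the ligand — the quantity
#' used as the enthalpic descriptor of the scoring function. The sum runs
#' over whatever pairs the calculation produced; fragments sharing no pair
#' with the target contribute zero.
#'
#' @param system an \linkS4class{FmoSystem}.
#' @param fragment fragment index (defaults to the designated ligand).
#' @return sum of PIEs, kcal/mol.
#' @examples
#' gen <- makeSyntheticFmoLog(6, ligandIndex = 3, seed = 42)
#' pieSum(gen$system, 3)
#' @export
pieSum <- function(system, fragment = ligandIndex(system)) {
  fr <- fmoFragments(system)
  if (length(fragment) != 1L || is.na(fragment) ||
      fragment < 1L || fragment > nrow(fr))
    stop("invalid fragment index", call. = FALSE)
  pr <- fmoPairs(system)
  sum(pr$pie[pr$i == fragment | pr$j == fragment])
}

#' Gas-phase binding enthalpy by the supermolecule method
#'
#' The alternative to PIE summation: three separate total-energy
#' calculations, with the binding enthalpy as
#' \eqn{\Delta H = E_{complex} - (E_{receptor} + E_{ligand})}, converted
#' from Hartree to kcal/mol.
#'
#' @param complexE,receptorE,ligandE total energies, Hartree.
#' @return binding enthalpy, kcal/mol.
#' @examples
#' supermoleculeEnthalpy(-3.5, -1.0, -2.0)  # -0.5 Ha = -313.75475 kcal/mol
#' @export
supermoleculeEnthalpy <- function(complexE, receptorE, ligandE) {
  stopifnot(is.finite(complexE), is.finite(receptorE), is.finite(ligandE))
  (complexE - (receptorE + ligandE)) * .HARTREE_KCAL
}

#' Build the inter-fragment interaction energy (IFIE) map
#'
#' Arranges the pair interaction energies as a symmetric N x N matrix with
#' zero diagonal (missing pairs are zero), the two-dimensional "IFIE map"
#' used to spot hot-spot residues. When the system has a designated ligand,
#' the ligand row is also returned ranked most-stabilising first.
#'
#' @param system an \linkS4class{FmoSystem}.
#' @return list with \code{matrix} (N x N, kcal/mol, dimnames = fragment
#'   labels) and \code{ranking} (data.frame of partner fragments of the
#'   ligand sorted by ascending PIE, or \code{NULL} when no ligand is set).
#' @examples
#' gen <- makeSyntheticFmoLog(5, ligandIndex = 5, seed = 3)
#' m <- ifieMap(gen$system)
#' m$ranking
#' @export
ifieMap <- function(system) {
  fr <- fmoFragments(system)
  pr <- fmoPairs(system)
  n <- nrow(fr)
  m <- matrix(0, n, n, dimnames = list(fr$label, fr$label))
  if (nrow(pr) > 0) {
    m[cbind(pr$i, pr$j)] <- pr$pie
    m[cbind(pr$j, pr$i)] <- pr$pie
  }
  ranking <- NULL
  li <- ligandIndex(system)
  if (!is.na(li)) {
    partners <- setdiff(seq_len(n), li)
    ranking <- data.frame(index = partners,
                          label = fr$label[partners],
                          pie = m[li, partners])
    ranking <- ranking[order(ranking$pie), , drop = FALSE]
    rownames(ranking) <- NULL
  }
  list(matrix = m, ranking = ranking)
}

#' Write an IFIE map and residue ranking to CSV
#'
#' @param system an \linkS4class{FmoSystem}.
#' @param matrixFile path for the N x N matrix CSV.
#' @param rankingFile optional path for the ranked ligand-row CSV (requires
#'   a designated ligand).
#' @return the [ifieMap()] result, invisibly.
#' @export
writeIfieMap <- function(system, matrixFile, rankingFile = NULL) {
  m <- ifieMap(system)
  utils::write.csv(m$matrix, matrixFile, row.names = TRUE)
  if (!is.null(rankingFile)) {
    if (is.null(m$ranking))
      stop("no ligand fragment designated; cannot write ranking")
    utils::write.csv(m$ranking, rankingFile, row.names = FALSE)
  }
  invisible(m)
}
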