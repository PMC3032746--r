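#' The fmoscore FMO log dialect
#'
#' The package reads a compact, versioned text rendering of the tables an
#' FMO program prints after a fragment calculation: a monomer block (one row
#' per fragment: index, label, SCF energy in Hartree) and a pair block (one
#' row per computed dimer). Two dialects are supported, reflecting the two
#' program eras whose outputs differ in pair-block column order:
#'
#' \describe{
#'   \item{\code{v2009}}{pair rows are \code{I J E(IJ)/Hartree PIE/kcal
#'     [ES EX CT DI]}}
#'   \item{\code{v2008}}{pair rows are \code{I J PIE/kcal E(IJ)/Hartree
#'     [ES EX CT DI]}}
#' }
#'
#' The dimer-energy column may be absent (3- or 7-column rows); the four
#' energy decomposition components (kcal/mol) are optional. Monomer and
#' dimer energies are in Hartree; pair interaction energies and components
#' in kcal/mol.
#'
#' @name fmo-log-dialect
#' @keywords internal
NULL

.restoreSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.withSeed <- function(seed, expr) {
  old <- .restoreSeed()
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Construct an FmoSystem from its parts
#'
#' @param fragments data.frame with columns \code{index}, \code{label},
#'   \code{energy} (Hartree).
#' @param pairs data.frame with columns \code{i}, \code{j}, \code{pie}
#'   (kcal/mol) and optionally \code{dimer_energy} (Hartree) and the
#'   component columns \code{es}, \code{ex}, \code{ct}, \code{di}.
#' @param ligandIndex ligand fragment index, or \code{NA}.
#' @return a validated \linkS4class{FmoSystem}.
#' @examples
#' FmoSystem(
#'   fragments = data.frame(index = 1:2, label = c("RES1", "LIG"),
#'                          energy = c(-1.0, -2.0)),
#'   pairs = data.frame(i = 1L, j = 2L, pie = -3.2),
#'   ligandIndex = 2L)
#' @export
FmoSystem <- function(fragments, pairs = NULL, ligandIndex = NA_integer_) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    pairs <- data.frame(i = integer(), j = integer(),
                        dimer_energy = numeric(), pie = numeric(),
                        es = numeric(), ex = numeric(), ct = numeric(),
                        di = numeric())
  for (col in c("dimer_energy", "es", "ex", "ct", "di"))
    if (is.null(pairs[[col]])) pairs[[col]] <- NA_real_
  pairs <- pairs[, c("i", "j", "dimer_energy", "pie", "es", "ex", "ct", "di")]
  pairs$i <- as.integer(pairs$i); pairs$j <- as.integer(pairs$j)
  fragments$index <- as.integer(fragments$index)
  fragments$label <- as.character(fragments$label)
  new("FmoSystem", fragments = fragments, pairs = pairs,
      ligandIndex = as.integer(ligandIndex))
}

#' Generate a synthetic FMO log with known ground truth
#'
#' Writes a well-formed log in the package's FMO dialect (see
#' \link{fmo-log-dialect}) whose monomer energies, dimer energies, pair
#' interaction energies and decomposition components are drawn reproducibly
#' from a seed, and returns both the text and the exact
#' \linkS4class{FmoSystem} written into it. Dimer energies are constructed
#' as \eqn{E_{IJ} = E_I + E_J + \Delta E_{IJ}} (with the PIE converted to
#' Hartree) and the four components are drawn so that ES + EX + CT + DI
#' equals the total PIE exactly, so the generated system satisfies every
#' invariant the parser checks.
#'
#' @param nFragments number of fragments (>= 2); all n(n-1)/2 pairs are
#'   written.
#' @param ligandIndex which fragment is the ligand (labelled \code{LIG});
#'   the others are labelled \code{RES<i>}.
#' @param seed integer; generation is bit-identical per seed.
#' @param energyScale typical magnitude of monomer energies, Hartree.
#' @param pieScale standard deviation of pair interaction energies, kcal/mol.
#' @param components write the four PIEDA-style component columns?
#' @param dimerEnergies write the dimer-energy column?
#' @param dialect \code{"v2009"} or \code{"v2008"} column order.
#' @return list with elements \code{log} (character vector of lines) and
#'   \code{system} (the ground-truth \linkS4class{FmoSystem}).
#' @examples
#' gen <- makeSyntheticFmoLog(nFragments = 4, ligandIndex = 4, seed = 1)
#' sys <- parseFmoOutput(gen$log, ligand = "LIG")
#' all.equal(fmoPairs(sys)$pie, fmoPairs(gen$system)$pie)
#' @export
makeSyntheticFmoLog <- function(nFragments, ligandIndex = nFragments,
                                seed = 1L, energyScale = 100,
                                pieScale = 5, components = TRUE,
                                dimerEnergies = TRUE,
                                dialect = c("v2009", "v2008")) {
  dialect <- match.arg(dialect)
  if (nFragments < 2L) stop("nFragments must be >= 2")
  if (ligandIndex < 1L || ligandIndex > nFragments)
    stop("ligandIndex out of range 1..", nFragments)
  n <- as.integer(nFragments)
  .withSeed(seed, {
    e_mono <- -energyScale * (1 + stats::runif(n))
    idx <- utils::combn(n, 2)
    np <- ncol(idx)
    pie <- round(stats::rnorm(np, 0, pieScale), 10)
    es <- round(stats::rnorm(np, 0, pieScale / 2), 10)
    ex <- round(abs(stats::rnorm(np, 0, pieScale / 3)), 10)
    ct <- round(stats::rnorm(np, 0, pieScale / 4), 10)
  })
  e_mono <- round(e_mono, 10)
  di <- round(pie - es - ex - ct, 10)
  pie <- es + ex + ct + di  # exact component sum after rounding
  dimer <- round(e_mono[idx[1, ]] + e_mono[idx[2, ]] + pie / .HARTREE_KCAL, 10)
  labels <- paste0("RES", seq_len(n))
  labels[ligandIndex] <- "LIG"
  fragments <- data.frame(index = seq_len(n), label = labels,
                          energy = e_mono)
  pairs <- data.frame(i = idx[1, ], j = idx[2, ],
                      dimer_energy = if (dimerEnergies) dimer else NA_real_,
                      pie = pie,
                      es = if (components) es else NA_real_,
                      ex = if (components) ex else NA_real_,
                      ct = if (components) ct else NA_real_,
                      di = if (components) di else NA_real_)
  system <- FmoSystem(fragments, pairs, ligandIndex)
  list(log = writeFmoLog(system, dialect = dialect), system = system)
}

#' Render an FmoSystem as log text
#'
#' Inverse of [parseFmoOutput()]: writes the monomer and pair blocks of the
#' package's FMO dialect (see \link{fmo-log-dialect}) at 10 decimal places,
#' enough for a lossless (1e-9) round trip.
#'
#' @param system an \linkS4class{FmoSystem}.
#' @param dialect pair-block column order, \code{"v2009"} or \code{"v2008"}.
#' @return character vector of lines.
#' @export
writeFmoLog <- function(system, dialect = c("v2009", "v2008")) {
  dialect <- match.arg(dialect)
  fr <- fmoFragments(system)
  pr <- fmoPairs(system)
  out <- c(
    sprintf("FMO INTERACTION ANALYSIS (fmoscore dialect %s)", dialect),
    sprintf("NFRAGS= %d", nrow(fr)),
    "",
    "MONOMER ENERGIES",
    sprintf("%5d  %-10s %20.10f", fr$index, fr$label, fr$energy),
    "END MONOMER ENERGIES"
  )
  if (nrow(pr) > 0) {
    has_dimer <- !all(is.na(pr$dimer_energy))
    has_comp <- !all(is.na(pr$es))
    fmt_row <- function(k) {
      base <- sprintf("%5d %5d", pr$i[k], pr$j[k])
      en <- character()
      if (has_dimer) {
        two <- c(sprintf("%20.10f", pr$dimer_energy[k]),
                 sprintf("%18.10f", pr$pie[k]))
        en <- if (dialect == "v2009") two else rev(two)
      } else {
        en <- sprintf("%18.10f", pr$pie[k])
      }
      comp <- if (has_comp)
        sprintf("%16.10f", c(pr$es[k], pr$ex[k], pr$ct[k], pr$di[k]))
      else character()
      paste(c(base, en, comp), collapse = " ")
    }
    out <- c(out, "", "PAIR INTERACTION ENERGIES",
             vapply(seq_len(nrow(pr)), fmt_row, character(1)),
             "END PAIR INTERACTION ENERGIES")
  }
  out
}
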