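#' Parse FMO program output into an FmoSystem
#'
#' Reads the monomer-energy and pair-interaction blocks of an FMO log (see
#' \link{fmo-log-dialect} for the format and the two supported column
#' orders) and returns a validated \linkS4class{FmoSystem}. When a
#' \code{ligand} label is supplied, the matching fragment is designated the
#' ligand, which is what [pieSum()] and the scoring workflow use to form the
#' gas-phase binding enthalpy.
#'
#' @param text character vector of log lines, or a single string containing
#'   newlines, or a file path (when \code{length(text) == 1} and the file
#'   exists).
#' @param ligand optional fragment label (e.g. \code{"LIG"}) to designate as
#'   the ligand; an error listing the available labels is raised when no
#'   fragment matches.
#' @param dialect pair-block column order; see \link{fmo-log-dialect}.
#' @return an \linkS4class{FmoSystem}; systems with a monomer block but no
#'   pair block are returned with zero pairs.
#' @examples
#' gen <- makeSyntheticFmoLog(3, seed = 2)
#' parseFmoOutput(gen$log, ligand = "LIG")
#' @export
parseFmoOutput <- function(text, ligand = NULL,
                           dialect = c("v2009", "v2008")) {
  dialect <- match.arg(dialect)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else if (length(text) == 1L)
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]

  perr <- function(lineno, msg)
    stop("FMO parse error at line ", lineno, ": ", msg, call. = FALSE)

  mono_start <- grep("^\\s*MONOMER ENERGIES\\s*$", text)
  if (length(mono_start) != 1L)
    perr(1L, "expected exactly one MONOMER ENERGIES block")
  mono_end <- grep("^\\s*END MONOMER ENERGIES\\s*$", text)
  if (length(mono_end) != 1L || mono_end < mono_start)
    perr(mono_start, "MONOMER ENERGIES block is not terminated")

  fragments <- .parseMonomerBlock(text, mono_start, mono_end, perr)

  pair_start <- grep("^\\s*PAIR INTERACTION ENERGIES\\s*$", text)
  if (length(pair_start) > 1L)
    perr(pair_start[2], "multiple pair blocks")
  if (length(pair_start) == 1L) {
    pair_end <- grep("^\\s*END PAIR INTERACTION ENERGIES\\s*$", text)
    if (length(pair_end) != 1L || pair_end < pair_start)
      perr(pair_start, "PAIR INTERACTION ENERGIES block is not terminated")
    pairs <- .parsePairBlock(text, pair_start, pair_end, dialect, perr)
  } else {
    pairs <- NULL
  }

  li <- NA_integer_
  if (!is.null(ligand)) {
    hit <- which(fragments$label == ligand)
    if (length(hit) == 0L)
      stop("no fragment labelled '", ligand, "'; available labels: ",
           paste(fragments$label, collapse = ", "), call. = FALSE)
    li <- hit[1]
  }

  sys <- FmoSystem(fragments, pairs, li)
  # surface duplicate pairs and dangling indices as validation errors
  v <- validObject(sys, test = TRUE)
  if (!isTRUE(v))
    stop("FMO validation error: ", paste(v, collapse = "; "), call. = FALSE)
  sys
}

.parseMonomerBlock <- function(text, start, end, perr) {
  body <- seq(start + 1L, end - 1L)
  body <- body[nzchar(trimws(text[body]))]
  if (length(body) == 0L) perr(start, "empty monomer block")
  idx <- integer(length(body)); lab <- character(length(body))
  en <- numeric(length(body))
  for (k in seq_along(body)) {
    tok <- strsplit(trimws(text[body[k]]), "\\s+")[[1]]
    if (length(tok) != 3L)
      perr(body[k], "monomer row must have 3 fields (index label energy)")
    i <- suppressWarnings(as.integer(tok[1]))
    e <- suppressWarnings(as.numeric(tok[3]))
    if (is.na(i) || is.na(e))
      perr(body[k], "malformed monomer row")
    idx[k] <- i; lab[k] <- tok[2]; en[k] <- e
  }
  if (!identical(sort(idx), seq_along(idx)))
    perr(start, "monomer indices must be unique and contiguous from 1")
  ord <- order(idx)
  data.frame(index = idx[ord], label = lab[ord], energy = en[ord])
}

.parsePairBlock <- function(text, start, end, dialect, perr) {
  body <- seq(start + 1L, end - 1L)
  body <- body[nzchar(trimws(text[body]))]
  n <- length(body)
  if (n == 0L)
    return(NULL)
  i <- j <- integer(n)
  dimer <- pie <- es <- ex <- ct <- di <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    tok <- strsplit(trimws(text[body[k]]), "\\s+")[[1]]
    nv <- length(tok) - 2L
    if (!nv %in% c(1L, 2L, 5L, 6L))
      perr(body[k], "pair row must have 3, 4, 7 or 8 fields")
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals)) perr(body[k], "malformed pair row")
    i[k] <- as.integer(vals[1]); j[k] <- as.integer(vals[2])
    rest <- vals[-(1:2)]
    if (nv %in% c(2L, 6L)) {
      if (dialect == "v2009") { dimer[k] <- rest[1]; pie[k] <- rest[2] }
      else                    { pie[k] <- rest[1]; dimer[k] <- rest[2] }
      rest <- rest[-(1:2)]
    } else {
      pie[k] <- rest[1]
      rest <- rest[-1]
    }
    if (length(rest) == 4L) {
      es[k] <- rest[1]; ex[k] <- rest[2]; ct[k] <- rest[3]; di[k] <- rest[4]
      if (abs(es[k] + ex[k] + ct[k] + di[k] - pie[k]) > 0.01)
        perr(body[k], sprintf(
          "components sum to %.4f but PIE is %.4f (tolerance 0.01 kcal/mol)",
          es[k] + ex[k] + ct[k] + di[k], pie[k]))
    }
  }
  data.frame(i = i, j = j, dimer_energy = dimer, pie = pie,
             es = es, ex = ex, ct = ct, di = di)
}
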