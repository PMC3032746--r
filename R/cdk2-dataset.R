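#' Load the bundled 28-compound CDK2 inhibitor reference set
#'
#' Returns the CDK2 inhibitor series that the package's reference PLS model
#' is built on: 28 compounds from one lead-optimisation campaign, 14 with
#' their own X-ray crystal structure (the training set) and 14 modelled into
#' a template structure (the test set). Each record carries the measured
#' IC50, the four scoring-function descriptors (gas-phase FMO enthalpy,
#' polar and nonpolar solvation, rotatable-bond entropy, all kcal/mol), the
#' IC50-derived experimental binding free energy, and the reference model's
#' reported prediction and residual.
#'
#' The loader validates an md5 checksum stored in the file header and a set
#' of internal-consistency invariants (row counts, train/test split sizes,
#' residual identity, IC50-to-free-energy agreement) before returning, so a
#' corrupted installation fails loudly rather than silently skewing a fit.
#'
#' @param path optional override of the bundled CSV location (for testing).
#' @return A data.frame with 28 rows and columns \code{entry},
#'   \code{pdb_code}, \code{modelled}, \code{resolution}, \code{ic50_uM},
#'   \code{role} (\code{"train"} or \code{"test"}), \code{dH_gas},
#'   \code{dG_psolv}, \code{dG_npsolv}, \code{TdS}, \code{dG_experimental},
#'   \code{dG_predicted_reported}, \code{residual_reported}.
#' @examples
#' cdk2 <- loadCdk2Dataset()
#' table(cdk2$role)
#' head(cdk2[, c("entry", "pdb_code", "ic50_uM", "dG_experimental")])
#' @export
loadCdk2Dataset <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cdk2_dataset.csv", package = "fmoscore",
                        mustWork = TRUE)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  md5_line <- grep("^# md5 ", lines, value = TRUE)
  if (length(md5_line) != 1L)
    stop("dataset integrity error: missing md5 checksum line")
  stored <- sub("^# md5 ", "", md5_line)
  data_lines <- lines[!is_comment]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(data_lines, tf)
  actual <- unname(tools::md5sum(tf))
  if (!identical(actual, stored))
    stop("dataset integrity error: md5 checksum mismatch (stored ", stored,
         ", actual ", actual, ")")
  d <- utils::read.csv(tf, stringsAsFactors = FALSE,
                       colClasses = c(pdb_code = "character"))
  .validateCdk2(d)
  d
}

.validateCdk2 <- function(d) {
  fail <- function(msg) stop("dataset integrity error: ", msg)
  if (nrow(d) != 28L) fail("expected 28 records")
  if (sum(d$role == "train") != 14L || sum(d$role == "test") != 14L)
    fail("expected a 14/14 train/test split")
  if (!identical(d$entry, 1:28)) fail("entry ids must be 1..28")
  res_err <- abs(d$residual_reported -
                 (d$dG_experimental - d$dG_predicted_reported))
  if (max(res_err) > 0.002)
    fail("residual_reported != dG_experimental - dG_predicted_reported")
  conv_err <- abs(dgFromIc50(d$ic50_uM) - d$dG_experimental)
  if (max(conv_err) > 0.02)
    fail("dG_experimental inconsistent with IC50 conversion")
  if (any(d$TdS != round(d$TdS) | d$TdS < 0 | d$TdS > 7))
    fail("TdS must be an integer count in 0..7")
  if (any(!is.na(d$resolution) & d$role == "test") ||
      any(is.na(d$resolution) & d$role == "train"))
    fail("resolution must be present exactly for the X-ray (training) entries")
  invisible(TRUE)
}

#' Extract the descriptor matrix and response from a CDK2-style table
#'
#' Convenience split of a compound table into the 4-column descriptor matrix
#' used by the PLS engine and the experimental free-energy response.
#'
#' @param d a data.frame as returned by [loadCdk2Dataset()].
#' @param role optional filter, \code{"train"} or \code{"test"}.
#' @return list with elements \code{X} (matrix, columns \code{dH_gas},
#'   \code{dG_psolv}, \code{dG_npsolv}, \code{TdS}, rownames = entry ids)
#'   and \code{y} (named numeric, kcal/mol).
#' @examples
#' tr <- descriptorMatrix(loadCdk2Dataset(), role = "train")
#' dim(tr$X)
#' @export
descriptorMatrix <- function(d, role = NULL) {
  if (!is.null(role)) {
    role <- match.arg(role, c("train", "test"))
    d <- d[d$role == role, , drop = FALSE]
  }
  X <- as.matrix(d[, c("dH_gas", "dG_psolv", "dG_npsolv", "TdS")])
  rownames(X) <- d$entry
  list(X = X, y = stats::setNames(d$dG_experimental, d$entry))
}
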