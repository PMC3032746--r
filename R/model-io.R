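#' Serialize a PLS model to JSON and back
#'
#' Stores the autoscaling parameters, NIPALS latent structure and raw-scale
#' regression coefficients so a fitted model can be archived and reapplied
#' without refitting.
#'
#' @param model a \linkS4class{PlsModel}.
#' @param path file path for the JSON.
#' @return \code{writePlsModel} returns \code{path} invisibly;
#'   \code{readPlsModel} returns the reconstructed
#'   \linkS4class{PlsModel}.
#' @examples
#' tr <- descriptorMatrix(loadCdk2Dataset(), "train")
#' m <- fitPls(tr$X, tr$y)
#' f <- tempfile(fileext = ".json")
#' writePlsModel(m, f)
#' m2 <- readPlsModel(f)
#' all.equal(coef(m), coef(m2))
#' @export
writePlsModel <- function(model, path) {
  obj <- list(
    format = "fmoscore-pls-model-v1",
    n_components = model@nComponents,
    columns = model@columns,
    x_means = unname(model@xMeans),
    x_sds = unname(model@xSds),
    y_mean = model@yMean,
    y_sd = model@ySd,
    weights = unname(model@weights),
    x_loadings = unname(model@xLoadings),
    y_loadings = model@yLoadings,
    coefficients = unname(model@coefficients),
    intercept = model@intercept)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePlsModel
#' @export
readPlsModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fmoscore-pls-model-v1"))
    stop("not an fmoscore PLS model file: ", path, call. = FALSE)
  A <- as.integer(obj$n_components)
  cols <- obj$columns
  asm <- function(m) matrix(unlist(m), ncol = A,
                            dimnames = list(cols, paste0("comp", seq_len(A))))
  new("PlsModel",
      nComponents = A, columns = cols,
      xMeans = stats::setNames(obj$x_means, cols),
      xSds = stats::setNames(obj$x_sds, cols),
      yMean = obj$y_mean, ySd = obj$y_sd,
      weights = asm(obj$weights), xLoadings = asm(obj$x_loadings),
      yLoadings = obj$y_loadings,
      scores = matrix(numeric(0), 0, A),
      coefficients = stats::setNames(obj$coefficients, cols),
      intercept = obj$intercept,
      fitted = numeric(0))
}
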