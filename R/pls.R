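#' Autoscale a descriptor matrix
#'
#' Mean-centres each column and scales it to unit sample standard
#' deviation, the standard pretreatment before a PLS fit so each descriptor
#' contributes comparably regardless of its natural magnitude.
#'
#' @param X numeric matrix (no missing values, every column with nonzero
#'   variance).
#' @param means,sds optional pre-computed scaling parameters (used when
#'   applying a training-set scaling to new rows).
#' @return list with \code{scaled} (matrix), \code{means} and \code{sds}.
#' @examples
#' autoscale(cbind(a = 1:3, b = c(2, 4, 8)))$scaled
#' @export
autoscale <- function(X, means = NULL, sds = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("descriptor matrix contains missing values")
  if (is.null(means)) means <- colMeans(X)
  if (is.null(sds)) sds <- apply(X, 2, stats::sd)
  zero <- which(!is.finite(sds) | sds == 0)
  if (length(zero) > 0)
    stop("zero-variance column(s): ",
         paste(colnames(X)[zero] %||% zero, collapse = ", "), call. = FALSE)
  list(scaled = sweep(sweep(X, 2, means), 2, sds, "/"),
       means = means, sds = sds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a NIPALS partial least squares regression model
#'
#' Single-response PLS on autoscaled data. With one response the NIPALS
#' weight vector has the closed form \eqn{w \propto X^\top y}, which is
#' used directly (no inner iteration is needed); per component the score
#' \eqn{t = Xw}, X-loading \eqn{p = X^\top t / t^\top t} and y-loading
#' \eqn{c = t^\top y / t^\top t} are extracted and X and y are deflated.
#' The latent structure is collapsed to regression coefficients
#' \eqn{B = W (P^\top W)^{-1} c}, then back-transformed so the stored
#' coefficients apply to raw descriptor rows and return predictions in the
#' original response units.
#'
#' @param X numeric matrix of descriptors (rows = compounds).
#' @param y numeric response (here: binding free energy, kcal/mol).
#' @param nComponents number of latent components A (1 <= A <= ncol(X),
#'   A < nrow(X)).
#' @return a \linkS4class{PlsModel}.
#' @examples
#' d <- loadCdk2Dataset()
#' tr <- descriptorMatrix(d, "train")
#' m <- fitPls(tr$X, tr$y, nComponents = 2)
#' rSquared(tr$y, fitted(m))
#' @export
fitPls <- function(X, y, nComponents = 2L) {
  X <- as.matrix(X)
  A <- as.integer(nComponents)
  n <- nrow(X); p <- ncol(X)
  if (A < 1L || A > p) stop("nComponents must be in 1..ncol(X)")
  if (n <= A) stop("need more rows than components")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  cols <- colnames(X) %||% paste0("x", seq_len(p))
  sc <- autoscale(X)
  ym <- mean(y); ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) stop("response has zero variance")
  E <- sc$scaled
  f <- (y - ym) / ys
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  cvec <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("NIPALS breakdown: residual X carries no covariance with y ",
           "at component ", a, call. = FALSE)
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    pvec <- drop(crossprod(E, t)) / tt
    cc <- sum(t * f) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - cc * t
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; cvec[a] <- cc
  }
  B <- drop(W %*% solve(crossprod(P, W), cvec))
  braw <- ys * B / sc$sds
  b0 <- ym - sum(braw * sc$means)
  fitted_vals <- drop(X %*% braw) + b0
  dimnames(W) <- dimnames(P) <- list(cols, paste0("comp", seq_len(A)))
  new("PlsModel",
      nComponents = A, columns = cols,
      xMeans = stats::setNames(sc$means, cols),
      xSds = stats::setNames(sc$sds, cols),
      yMean = ym, ySd = ys,
      weights = W, xLoadings = P, yLoadings = cvec,
      scores = Tm,
      coefficients = stats::setNames(braw, cols),
      intercept = b0,
      fitted = stats::setNames(fitted_vals, rownames(X)))
}

#' Predict from a fitted PLS model
#'
#' Applies the stored autoscaling and regression coefficients to new raw
#' descriptor rows; nothing is refitted. Columns are matched by name when
#' the input carries names.
#'
#' @param object a \linkS4class{PlsModel}.
#' @param newdata matrix or data.frame with the model's descriptor columns
#'   (or a single named/unnamed row).
#' @param ... unused.
#' @return numeric predictions in the response's original units.
#' @aliases predict,PlsModel-method
#' @examples
#' d <- loadCdk2Dataset()
#' tr <- descriptorMatrix(d, "train")
#' m <- fitPls(tr$X, tr$y)
#' predict(m, descriptorMatrix(d, "test")$X)
#' @export
setMethod("predict", "PlsModel", function(object, newdata, ...) {
  X <- newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(newdata)))
  X <- as.matrix(X)
  p <- length(object@columns)
  if (!is.null(colnames(X))) {
    if (!all(object@columns %in% colnames(X)))
      stop("newdata lacks model column(s): ",
           paste(setdiff(object@columns, colnames(X)), collapse = ", "),
           call. = FALSE)
    X <- X[, object@columns, drop = FALSE]
  } else if (ncol(X) != p) {
    stop("newdata has ", ncol(X), " columns; model expects ", p,
         call. = FALSE)
  }
  if (anyNA(X)) stop("newdata contains missing values", call. = FALSE)
  drop(X %*% object@coefficients) + object@intercept
})

#' Goodness-of-fit and error statistics
#'
#' @description
#' \code{rSquared} is the coefficient of determination
#' \eqn{1 - SS_{res}/SS_{tot}} about the observed mean.
#'
#' \code{rmsee} is the root mean square error of estimation for a
#' training-set fit: \eqn{\sqrt{SS_{res}/(n - 1 - A)}}, charging one degree
#' of freedom for centring and one per latent component.
#'
#' \code{rmsep} is the root mean square error of prediction for an external
#' set: \eqn{\sqrt{SS_{res}/n}}.
#'
#' @param observed,fitted,predicted numeric vectors of equal length.
#' @param A number of latent components used in the fit.
#' @return a single number (\code{rSquared} unitless; \code{rmsee},
#'   \code{rmsep} in response units).
#' @examples
#' rSquared(c(1, 2, 3), c(1.1, 1.9, 3.0))
#' @export
rSquared <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("undefined statistic: observed values are constant",
                     call. = FALSE)
  1 - sum((observed - fitted)^2) / sst
}

#' @rdname rSquared
#' @export
rmsee <- function(observed, fitted, A) {
  n <- length(observed)
  stopifnot(n == length(fitted))
  if (n <= A + 1) stop("need n > A + 1 for the estimation error",
                       call. = FALSE)
  sqrt(sum((observed - fitted)^2) / (n - 1 - A))
}

#' @rdname rSquared
#' @export
rmsep <- function(observed, predicted) {
  n <- length(observed)
  stopifnot(n == length(predicted), n >= 1)
  sqrt(sum((observed - predicted)^2) / n)
}

#' Pearson and Spearman correlation of predictions with observations
#'
#' @param observed,predicted numeric vectors (length >= 3, both with
#'   nonzero variance). Ties receive average ranks in the Spearman
#'   statistic.
#' @return named numeric: \code{pearson_r}, \code{spearman_rho}.
#' @examples
#' rankCorrelations(1:5, c(1.2, 1.9, 3.3, 3.9, 5.1))
#' @export
rankCorrelations <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("undefined statistic: zero variance", call. = FALSE)
  c(pearson_r = stats::cor(observed, predicted),
    spearman_rho = stats::cor(observed, predicted, method = "spearman"))
}

#' Grouped cross-validation of a PLS model
#'
#' Splits the training rows into \code{nGroups} cross-validation groups,
#' refits the autoscaling and the PLS model with each group left out in
#' turn, predicts the held-out rows, and reports
#' \eqn{q^2 = 1 - PRESS/SS_{tot}} where PRESS is the predictive residual
#' sum of squares pooled over all folds and \eqn{SS_{tot}} is about the
#' full-set mean. The default grouping is deterministic round-robin by row
#' order (row k goes to group \code{(k-1) mod nGroups + 1}); a seeded
#' random partition is available.
#'
#' @param X descriptor matrix, \code{y} response (as in [fitPls()]).
#' @param y numeric response.
#' @param nComponents latent components per fold.
#' @param nGroups number of CV groups (<= rows).
#' @param scheme \code{"round_robin"} (default) or \code{"random"}.
#' @param seed integer seed, used only by the random scheme.
#' @return list with \code{q2}, \code{press}, \code{ss_total},
#'   \code{groups} (the assignment used) and \code{scheme}.
#' @examples
#' d <- loadCdk2Dataset()
#' tr <- descriptorMatrix(d, "train")
#' crossValidateQ2(tr$X, tr$y, nComponents = 2, nGroups = 7)$q2
#' @export
crossValidateQ2 <- function(X, y, nComponents = 2L, nGroups = 7L,
                            scheme = c("round_robin", "random"),
                            seed = 1L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  n <- nrow(X)
  if (nGroups < 2L || nGroups > n)
    stop("nGroups must be in 2..nrow(X)", call. = FALSE)
  groups <- switch(scheme,
    round_robin = ((seq_len(n) - 1L) %% nGroups) + 1L,
    random = .withSeed(seed, sample(((seq_len(n) - 1L) %% nGroups) + 1L)))
  if (any(tabulate(groups, nGroups) < 1L))
    stop("grouping error: empty cross-validation group", call. = FALSE)
  press <- 0
  for (g in seq_len(nGroups)) {
    hold <- groups == g
    m <- fitPls(X[!hold, , drop = FALSE], y[!hold], nComponents)
    pred <- predict(m, X[hold, , drop = FALSE])
    press <- press + sum((y[hold] - pred)^2)
  }
  sst <- sum((y - mean(y))^2)
  list(q2 = 1 - press / sst, press = press, ss_total = sst,
       groups = groups, scheme = scheme)
}

#' Fit, validate and test a PLS scoring model in one call
#'
#' The full modelling workflow: fit a PLS model with \code{nComponents}
#' latent components on the training block, compute the training-fit
#' statistics (r2, RMSEE, Pearson and Spearman correlations), the grouped
#' cross-validation q2, and — when a test block is given — external
#' predictions with RMSEP and their correlations. The test-set Pearson
#' correlation is reported both unsquared (\code{test$pearson_r}) and
#' squared (\code{test$pearson_r2}) since conventions differ on which is
#' quoted as the test-set "r2".
#'
#' @param trainX,trainY training descriptor matrix and response.
#' @param testX,testY optional test block.
#' @param nComponents latent components.
#' @param nGroups,cvScheme,seed cross-validation settings, see
#'   [crossValidateQ2()].
#' @return list with elements \code{model} (\linkS4class{PlsModel}),
#'   \code{train} (r2, rmsee, q2, pearson_r, spearman_rho, fitted,
#'   residuals, press, cv_scheme) and, if a test block was supplied,
#'   \code{test} (rmsep, pearson_r, pearson_r2, spearman_rho, predicted,
#'   residuals).
#' @examples
#' d <- loadCdk2Dataset()
#' tr <- descriptorMatrix(d, "train"); te <- descriptorMatrix(d, "test")
#' rep <- evaluateModel(tr$X, tr$y, te$X, te$y)
#' rep$train$r2
#' @export
evaluateModel <- function(trainX, trainY, testX = NULL, testY = NULL,
                          nComponents = 2L, nGroups = 7L,
                          cvScheme = "round_robin", seed = 1L) {
  model <- fitPls(trainX, trainY, nComponents)
  f <- fitted(model)
  cv <- crossValidateQ2(trainX, trainY, nComponents, nGroups,
                        scheme = cvScheme, seed = seed)
  cors <- rankCorrelations(trainY, f)
  out <- list(
    model = model,
    train = list(
      r2 = rSquared(trainY, f),
      rmsee = rmsee(trainY, f, nComponents),
      q2 = cv$q2,
      press = cv$press,
      cv_scheme = cv$scheme,
      pearson_r = unname(cors["pearson_r"]),
      spearman_rho = unname(cors["spearman_rho"]),
      fitted = f,
      residuals = trainY - f))
  if (!is.null(testX)) {
    if (is.null(testY)) stop("testY required when testX is given")
    p <- predict(model, testX)
    tc <- rankCorrelations(testY, p)
    out$test <- list(
      rmsep = rmsep(testY, p),
      pearson_r = unname(tc["pearson_r"]),
      pearson_r2 = unname(tc["pearson_r"])^2,
      spearman_rho = unname(tc["spearman_rho"]),
      predicted = p,
      residuals = testY - p)
  }
  out
}
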