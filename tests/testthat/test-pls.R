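test_that("autoscaling centres and standardises every column", {
  sc <- autoscale(cbind(a = c(1, 2, 3)))
  expect_equal(unname(sc$scaled[, 1]), c(-1, 0, 1))
  # idempotence on already-scaled data
  again <- autoscale(sc$scaled)
  expect_equal(again$scaled, sc$scaled, tolerance = 1e-12)
  rr <- randomRegression(14, 4, seed = 2)
  sc2 <- autoscale(rr$X)
  expect_lt(max(abs(colSums(sc2$scaled) / 14)), 1e-10)
  expect_equal(unname(apply(sc2$scaled, 2, sd)), rep(1, 4),
               tolerance = 1e-12)
  # inverse transform recovers the input
  back <- sweep(sweep(sc2$scaled, 2, sc2$sds, "*"), 2, sc2$means, "+")
  expect_equal(back, rr$X, tolerance = 1e-12)
  expect_error(autoscale(cbind(a = 1:3, b = rep(2, 3))), "b")
})

test_that("a response along one latent direction is fit perfectly by one component", {
  # columns orthogonal after centring, response equal to the first: the
  # single NIPALS component aligns exactly with it
  rr <- randomRegression(20, 3, seed = 5)
  X <- rr$X
  x1 <- X[, 1] - mean(X[, 1])
  for (j in 2:3) X[, j] <- stats::resid(lm(X[, j] ~ x1))
  y <- X[, 1]
  m <- fitPls(X, y, nComponents = 1)
  expect_equal(rSquared(y, fitted(m)), 1, tolerance = 1e-10)
})

test_that("full-rank PLS coincides with ordinary least squares", {
  for (seed in 1:4) {
    rr <- randomRegression(14, 4, seed = seed)
    m <- fitPls(rr$X, rr$y, nComponents = 4)
    ols <- lm(rr$y ~ rr$X)
    expect_equal(unname(fitted(m)), unname(stats::fitted(ols)),
                 tolerance = 1e-8)
  }
})

test_that("score vectors are orthogonal and weights unit-norm", {
  rr <- randomRegression(30, 5, seed = 7)
  m <- fitPls(rr$X, rr$y, nComponents = 4)
  Tm <- m@scores
  G <- crossprod(Tm)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_equal(unname(sqrt(colSums(m@weights^2))), rep(1, 4),
               tolerance = 1e-12)
})

test_that("prediction applies stored scaling without refitting", {
  rr <- randomRegression(16, 4, seed = 9)
  m <- fitPls(rr$X, rr$y, nComponents = 2)
  expect_equal(unname(predict(m, rr$X)), unname(fitted(m)),
               tolerance = 1e-12)
  # a row of column means predicts the training mean of y
  expect_equal(unname(predict(m, colMeans(rr$X))), mean(rr$y),
               tolerance = 1e-10)
  expect_error(predict(m, rr$X[, 1:3]), "lacks model column")
  Xbad <- rr$X; colnames(Xbad) <- NULL
  expect_error(predict(m, Xbad[, 1:3, drop = FALSE]), "model expects")
})

test_that("predictions are equivariant under affine rescaling of y", {
  rr <- randomRegression(18, 4, seed = 3)
  m1 <- fitPls(rr$X, rr$y, nComponents = 2)
  m2 <- fitPls(rr$X, 2.5 * rr$y - 7, nComponents = 2)
  newX <- randomRegression(5, 4, seed = 30)$X
  expect_equal(predict(m2, newX), 2.5 * predict(m1, newX) - 7,
               tolerance = 1e-8)
})

test_that("error statistics follow their defining formulas", {
  obs <- c(1, 2, 3, 5)
  expect_equal(rSquared(obs, obs), 1)
  expect_equal(rSquared(obs, rep(mean(obs), 4)), 0)
  expect_error(rSquared(rep(1, 3), c(1, 1, 2)), "constant")
  fit <- obs + c(0.1, -0.2, 0.05, 0)
  expect_equal(rmsee(obs, fit, A = 2),
               sqrt(sum((obs - fit)^2) / (4 - 1 - 2)))
  expect_equal(rmsee(obs, obs, A = 2), 0)
  expect_error(rmsee(obs[1:3], fit[1:3], A = 2), "n > A")
  expect_equal(rmsep(obs, fit), sqrt(mean((obs - fit)^2)))
  expect_equal(rmsep(obs, obs), 0)
})

test_that("rank correlations handle perfect, reversed and tied orderings", {
  expect_equal(unname(rankCorrelations(1:5, 1:5)), c(1, 1))
  expect_equal(unname(rankCorrelations(1:5, 5:1)), c(-1, -1))
  r <- rankCorrelations(c(1, 2, 3, 4), c(1.1, 2.2, 2.2, 3.9))
  expect_true(r["spearman_rho"] < 1)  # average ranks for the tie
  expect_error(rankCorrelations(rep(1, 3), 1:3), "zero variance")
})

test_that("cross-validation recovers a noiseless linear response exactly", {
  rr <- randomRegression(21, 4, sigma = 0, seed = 11)
  cv <- crossValidateQ2(rr$X, rr$y, nComponents = 4, nGroups = 7)
  expect_equal(cv$q2, 1, tolerance = 1e-8)
})

test_that("permuting the response destroys cross-validated predictivity", {
  tr <- descriptorMatrix(loadCdk2Dataset(), "train")
  yperm <- withr::with_seed(13, sample(tr$y))
  cv <- crossValidateQ2(tr$X, yperm, nComponents = 2, nGroups = 7)
  expect_lt(cv$q2, 0.3)
})

test_that("cross-validation grouping is validated and stamped", {
  rr <- randomRegression(10, 3, seed = 1)
  expect_error(crossValidateQ2(rr$X, rr$y, nGroups = 11), "2..nrow")
  cv <- crossValidateQ2(rr$X, rr$y, nComponents = 2, nGroups = 5)
  expect_equal(cv$scheme, "round_robin")
  expect_equal(cv$groups, rep(1:5, 2))
  cvr <- crossValidateQ2(rr$X, rr$y, nComponents = 2, nGroups = 5,
                         scheme = "random", seed = 4)
  expect_equal(sort(tabulate(cvr$groups, 5)), rep(2L, 5))
})

test_that("evaluateModel recovers known structure from noisy simulation", {
  rr <- randomRegression(200, 4, sigma = 0.8, seed = 17)
  test <- randomRegression(200, 4, sigma = 0.8, seed = 18)
  ytest <- drop(test$X %*% rr$beta) + withr::with_seed(19, rnorm(200, 0, 0.8))
  rep <- evaluateModel(rr$X, rr$y, test$X, ytest, nComponents = 4)
  expect_lt(abs(rep$test$rmsep - 0.8) / 0.8, 0.3)
  # noiseless train = test: everything perfect
  noiseless <- randomRegression(30, 4, sigma = 0, seed = 23)
  rep0 <- evaluateModel(noiseless$X, noiseless$y, noiseless$X, noiseless$y,
                        nComponents = 4)
  expect_equal(rep0$train$r2, 1, tolerance = 1e-10)
  expect_equal(rep0$test$rmsep, 0, tolerance = 1e-8)
  expect_equal(rep0$test$pearson_r, 1, tolerance = 1e-10)
})

test_that("q2 does not exceed r2 on the bundled training set", {
  tr <- descriptorMatrix(loadCdk2Dataset(), "train")
  rep <- evaluateModel(tr$X, tr$y, nComponents = 2)
  expect_lt(rep$train$q2, rep$train$r2)
})

test_that("the NIPALS fit agrees with an independent PLS implementation", {
  tr <- descriptorMatrix(loadCdk2Dataset(), "train")
  m <- fitPls(tr$X, tr$y, nComponents = 2)
  ref <- mixOmics::pls(tr$X, tr$y, ncomp = 2, mode = "regression",
                       scale = TRUE)
  ref_fit <- drop(stats::predict(ref, tr$X)$predict[, 1, 2])
  expect_equal(unname(fitted(m)), unname(ref_fit), tolerance = 1e-6)
})

test_that("models serialize to JSON and back without loss", {
  tr <- descriptorMatrix(loadCdk2Dataset(), "train")
  m <- fitPls(tr$X, tr$y, nComponents = 2)
  f <- tempfile(fileext = ".json")
  writePlsModel(m, f)
  m2 <- readPlsModel(f)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_equal(predict(m2, tr$X), predict(m, tr$X), tolerance = 1e-12)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "x"), bad, auto_unbox = TRUE)
  expect_error(readPlsModel(bad), "not an fmoscore")
})
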