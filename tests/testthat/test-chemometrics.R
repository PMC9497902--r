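test_that("the two-thirds row split reproduces the 110/55 group sizes", {
  sp <- splitCalibrationPrediction(165L, seed = 1L)
  expect_length(sp$calibration, 110L)
  expect_length(sp$prediction, 55L)
  expect_setequal(c(sp$calibration, sp$prediction), 1:165)
  expect_identical(sp, splitCalibrationPrediction(165L, seed = 1L))
  expect_false(identical(sp$calibration,
                         splitCalibrationPrediction(165L, seed = 2L)$calibration))
  expect_error(splitCalibrationPrediction(165L, fraction = 1.2), "\\(0, 1\\)")
})

test_that("grouped splitting keeps a sausage's regions together", {
  tab <- generateSpectraTable(9, noiseSd = 0, seed = 2)
  sp <- splitCalibrationPrediction(tab, seed = 3L, by = "sample")
  codes <- sampleCode(tab)
  expect_length(intersect(codes[sp$calibration], codes[sp$prediction]), 0L)
})

test_that("a single latent variable fits a rank-one problem exactly", {
  pr <- oneFactorProblem()
  fit <- fitPLSR(pr$X, pr$y, 1L)
  m <- computeMetrics(pr$y, predict(fit, pr$X))
  expect_equal(m$R2, 1, tolerance = 1e-8)
})

test_that("full-rank PLSR equals the normal-equations solution", {
  X <- withr::with_seed(13, matrix(rnorm(40), 10, 4))
  y <- withr::with_seed(14, rnorm(10))
  fit <- fitPLSR(X, y, 4L)
  expect_equal(predict(fit, X), olsOracle(X, y), tolerance = 1e-8)
})

test_that("NIPALS score vectors are mutually orthogonal", {
  tab <- generateSpectraTable(8, noiseSd = 0.05, seed = 4)
  fit <- fitPLSR(spectraMatrix(tab), pHRef(tab), 6L)
  G <- crossprod(fit@scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("the latent-variable path and the collapsed form agree", {
  tab <- generateSpectraTable(8, noiseSd = 0.05, seed = 5)
  X <- spectraMatrix(tab); y <- pHRef(tab)
  fit <- fitPLSR(X, y, 5L)
  Xc <- sweep(X, 2, fit@xMean)
  ## latent path: scores from weights via the deflation-equivalent projection
  Tnew <- Xc %*% fit@weights %*% solve(crossprod(fit@xLoadings, fit@weights))
  latent <- fit@yMean + as.numeric(Tnew %*% fit@yLoadings)
  expect_equal(latent, predict(fit, X), tolerance = 1e-10)
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fitPLSR(X, rep(1, 10), 1L), "zero-variance")
  expect_error(fitPLSR(X, rnorm(10), 5L), "nLatent")
  pr <- oneFactorProblem()           # rank-one X cannot support 3 LVs
  expect_error(fitPLSR(pr$X, pr$y, 3L), "rank")
})

test_that("prediction respects centering and the intercept", {
  tab <- generateSpectraTable(6, noiseSd = 0.05, seed = 6)
  fit <- fitPLSR(spectraMatrix(tab), pHRef(tab), 3L)
  Xm <- matrix(fit@xMean, 4, length(fit@xMean), byrow = TRUE)
  expect_equal(predict(fit, Xm), rep(fit@yMean, 4), tolerance = 1e-10)
  fit0 <- fit
  fit0@coef <- rep(0, length(fit@coef))
  expect_equal(predict(fit0, spectraMatrix(tab)), rep(fit0@b0, 30))
  expect_error(predict(fit, matrix(0, 2, 3)), "bands")
})

test_that("metrics follow the printed R2 and RMSE formulas", {
  y <- c(4, 5, 6); yh <- c(4, 5, 7)
  m <- computeMetrics(y, yh)
  expect_equal(m$RMSE, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(m$R2, 0.5, tolerance = 1e-12)
  perfect <- computeMetrics(y, y)
  expect_equal(perfect$R2, 1); expect_equal(perfect$RMSE, 0)
  expect_equal(computeMetrics(y, rep(mean(y), 3))$R2, 0)
  expect_error(computeMetrics(rep(2, 3), y), "zero variance")
})

test_that("cross-validation is exact on a noiseless linear problem", {
  X <- withr::with_seed(21, matrix(rnorm(25 * 4), 25, 4))
  beta <- c(1, -2, 0.5, 3)
  y <- 2 + as.numeric(X %*% beta)
  cv <- crossValidate(X, y, 4L, scheme = "loo")
  expect_lt(cv$RMSECV, 1e-6)
})

test_that("leave-one-out performs exactly n refits", {
  X <- withr::with_seed(22, matrix(rnorm(12 * 3), 12, 3))
  y <- withr::with_seed(23, rnorm(12))
  count <- 0L
  crossValidate(X, y, 2L, scheme = "loo",
                fitHook = function() count <<- count + 1L)
  expect_equal(count, 12L)
})

test_that("k-fold assignment is reproducible from its seed", {
  X <- withr::with_seed(24, matrix(rnorm(30 * 5), 30, 5))
  y <- withr::with_seed(25, rnorm(30))
  a <- crossValidate(X, y, 2L, scheme = "kfold", k = 5L, seed = 7L)
  b <- crossValidate(X, y, 2L, scheme = "kfold", k = 5L, seed = 7L)
  expect_identical(a, b)
  expect_error(crossValidate(X, y, 2L, scheme = "kfold", k = 31L), "exceeds")
})

test_that("latent-variable selection applies the 2% parsimony rule", {
  pr <- oneFactorProblem(n = 24L, p = 10L, seed = 31L)
  noisy <- pr$X + withr::with_seed(32, matrix(rnorm(240, 0, 1e-4), 24, 10))
  sel <- selectNLatent(noisy, pr$y, maxLv = 5L)
  expect_equal(sel$nLatent, 1L)
  expect_equal(selectNLatent(noisy, pr$y, maxLv = 1L)$nLatent, 1L)
})

test_that("adding pure-noise bands does not inflate training RMSE", {
  tab <- generateSpectraTable(10, noiseSd = 0.1, seed = 41)
  X <- spectraMatrix(tab)[, seq(1, 151, by = 10)]
  y <- pHRef(tab)
  base <- computeMetrics(y, predict(fitPLSR(X, y, 4L), X))$RMSE
  Xplus <- cbind(X, withr::with_seed(42, matrix(rnorm(50 * 8, 0, 0.01),
                                                50, 8)))
  plus <- computeMetrics(y, predict(fitPLSR(Xplus, y, 4L), Xplus))$RMSE
  expect_lte(plus, base + 1e-8)
})

test_that("chain metrics report the six-number record with the CV gap flag", {
  tab <- generateSpectraTable(10, noiseSd = 0.02, seed = 43)
  sp <- splitCalibrationPrediction(tab, seed = 44L)
  rec <- chainMetrics(tab, "Raw", sp, 6L, cvScheme = "kfold")
  expect_named(rec, c("domain", "treatment", "n_latent", "Rc2", "RMSEC",
                      "Rp2", "RMSEP", "Rcv2", "RMSECV", "good_model"))
  expect_gte(rec$RMSEC, 0)
  expect_lte(rec$Rc2, 1)
  expect_true(rec$good_model)  # near-noiseless linear truth fits well
})

test_that("PLSR models round-trip through JSON", {
  tab <- generateSpectraTable(6, noiseSd = 0.05, seed = 45)
  fit <- fitPLSR(spectraMatrix(tab), pHRef(tab), 3L,
                 wavelengthsNm = wavelengths(tab))
  path <- tempfile(fileext = ".json")
  writeModelJSON(fit, path)
  back <- readModelJSON(path)
  expect_equal(back@coef, fit@coef, tolerance = 1e-12)
  expect_equal(back@b0, fit@b0, tolerance = 1e-12)
  expect_equal(predict(back, spectraMatrix(tab)),
               predict(fit, spectraMatrix(tab)), tolerance = 1e-12)
})
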