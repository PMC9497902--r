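## Build a PLSRModel shell with a prescribed coefficient profile so extremum
## selection can be tested against planted ground truth.
coefModel <- function(b) {
  new("PLSRModel", nLatent = 1L, xMean = rep(0, length(b)), yMean = 0,
      weights = matrix(0, length(b), 1), xLoadings = matrix(0, length(b), 1),
      yLoadings = 0, scores = matrix(0, 0, 1), coef = b, b0 = 0,
      wavelengthsNm = rep(NA_real_, length(b)), chain = "Raw")
}

test_that("planted extrema are recovered exactly", {
  g <- defaultGrid()
  b <- rep(0, 151)
  centers <- c(4, 16, 28, 40, 52, 64, 76, 88, 100, 112, 124, 136)
  signs <- rep(c(1, -1), 6)
  for (i in seq_along(centers)) {
    idx <- centers[i] + (-3:3)
    b[idx] <- b[idx] + signs[i] * (10 + i) * exp(-0.5 * ((-3:3) / 1.5)^2)
  }
  fw <- selectFeatureWavelengths(coefModel(b), g, k = 12)
  expect_equal(fw, wavelengthOfBand(g, centers))
})

test_that("a monotone coefficient profile yields no extrema plus a warning", {
  g <- defaultGrid()
  expect_warning(fw <- selectFeatureWavelengths(coefModel(seq(0, 1,
                                                length.out = 151)), g),
                 "no interior extrema")
  expect_length(fw, 0L)
})

test_that("selection enforces subset-of-grid and pairwise separation", {
  g <- defaultGrid()
  b <- withr::with_seed(51, cumsum(rnorm(151)))  # wiggly profile
  sep <- 3L
  fw <- suppressWarnings(selectFeatureWavelengths(coefModel(b), g, k = 12,
                                                  minSeparationBands = sep))
  expect_true(all(fw %in% wavelengths(g)))
  if (length(fw) > 1)
    expect_true(all(diff(fw) >= sep * g@stepNm))
})

test_that("the published 12-wavelength preset evaluates as printed", {
  m <- presetReducedModel()
  expect_equal(wavelengths(m),
               c(365, 385, 405, 475, 525, 580, 640, 725, 875, 915, 1005,
                 1060))
  expect_equal(presetFeatureWavelengths(), wavelengths(m))
  expect_equal(evaluateLinearModel(m, rep(0, 12)), 5.335)
  r <- rep(0, 12); r[1] <- 1
  expect_equal(evaluateLinearModel(m, r), 5.335 + 7.243)
  expect_error(evaluateLinearModel(m, rep(0, 5)), "expected 12")
})

test_that("an intercept-only model returns its intercept", {
  m0 <- linearSpectralModel(5.1, numeric(0), numeric(0))
  expect_equal(evaluateLinearModel(m0, numeric(0)), 5.1)
})

test_that("restricting to all bands reproduces the full model", {
  tab <- generateSpectraTable(8, noiseSd = 0.05, seed = 52)
  sp <- splitCalibrationPrediction(tab, seed = 53L)
  M <- spectraMatrix(tab); y <- pHRef(tab)
  full <- fitPLSR(M[sp$calibration, ], y[sp$calibration], 5L)
  red <- buildReducedModel(tab, wavelengths(tab), sp, 5L)
  expect_equal(predict(red$plsr, M), predict(full, M), tolerance = 1e-10)
  expect_error(buildReducedModel(tab, c(365, 365, 405), sp, 2L),
               "duplicate")
})

test_that("reducing 151 bands to 12 removes 92% of wavelengths", {
  expect_equal(reductionPercent(151, 12), 92)
})

test_that("a 12-band generating rule loses little predictive power", {
  tab <- generateSpectraTable(33, noiseSd = 0.03, seed = 54)
  sp <- splitCalibrationPrediction(tab, seed = 55L)
  M <- spectraMatrix(tab); y <- pHRef(tab)
  full <- fitPLSR(M[sp$calibration, ], y[sp$calibration], 12L)
  fullRp2 <- computeMetrics(y[sp$prediction],
                            predict(full, M[sp$prediction, ]))$R2
  red <- buildReducedModel(tab, presetFeatureWavelengths(), sp, 12L)
  expect_gte(red$metrics$Rp2, fullRp2 - 0.02)
})

test_that("the collapsed linear form agrees with the PLSR path", {
  tab <- generateSpectraTable(10, noiseSd = 0.02, seed = 56)
  sp <- splitCalibrationPrediction(tab, seed = 57L)
  fw <- presetFeatureWavelengths()
  red <- buildReducedModel(tab, fw, sp, 8L)
  bands <- bandOfWavelength(spectralGrid(tab), fw)
  sub <- spectraMatrix(tab)[, bands]
  expect_equal(evaluateLinearModel(red$linear, sub),
               predict(red$plsr, sub), tolerance = 1e-10)
  ## pretreated reduced fits have no collapsed linear form
  redChain <- buildReducedModel(tab, fw, sp, 4L, chain = "SNV")
  expect_null(redChain$linear)
})

test_that("linear models round-trip through JSON with their formula", {
  m <- presetReducedModel()
  path <- tempfile(fileext = ".json")
  writeLinearModelJSON(m, path)
  back <- readLinearModelJSON(path)
  expect_equal(intercept(back), 5.335)
  expect_equal(regressionCoefficients(back), regressionCoefficients(m))
  expect_match(formulaString(back), "^pH = 5.335 \\+ 7.243 L365")
})
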