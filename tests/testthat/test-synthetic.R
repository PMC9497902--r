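test_that("the noiseless constant-pH phantom is deterministic and separable", {
  spec <- phantomSpec(nrow = 30L, ncol = 40L, pH = 5.2, gainSd = 0,
                      offsetSd = 0, noiseSd = 0, seed = 81L)
  ph <- generatePhantomHypercube(spec)
  v <- cubeValues(ph$cube)
  idx <- which(ph$mask)
  flat <- matrix(v, prod(dim(ph$mask)), dim(v)[3])
  sausage <- flat[idx, ]
  expect_lt(max(apply(sausage, 2, function(col) diff(range(col)))), 1e-12)
  band70 <- bandOfWavelength(spectralGrid(ph$cube), 695)
  expect_true(all(flat[-idx, band70] < 0.075))
  expect_true(all(flat[idx, band70] > 0.075))
})

test_that("phantom cubes are bit-reproducible from their seed", {
  a <- generatePhantomHypercube(phantomSpec(seed = 82L))
  b <- generatePhantomHypercube(phantomSpec(seed = 82L))
  expect_identical(cubeValues(a$cube), cubeValues(b$cube))
  c2 <- generatePhantomHypercube(phantomSpec(seed = 83L))
  expect_false(identical(cubeValues(a$cube), cubeValues(c2$cube)))
})

test_that("zero pH-coupling decouples the cube from the pH field", {
  feats <- hyperpH:::.defaultFeatures()
  feats$slope <- 0
  a <- generatePhantomHypercube(phantomSpec(pH = 4.6, features = feats,
                                            seed = 84L))
  b <- generatePhantomHypercube(phantomSpec(pH = 6.3, features = feats,
                                            seed = 84L))
  expect_identical(cubeValues(a$cube), cubeValues(b$cube))
})

test_that("a separability-violating spec is rejected", {
  expect_error(phantomSpec(background = 0.2) |> generatePhantomHypercube(),
               "separability")
})

test_that("phantom ground truth includes balanced regions and region pH", {
  ph <- generatePhantomHypercube(phantomSpec(pH = c(4.5, 6.4), seed = 85L))
  cnt <- tabulate(labelMatrix(ph$labels)[ph$mask], 5)
  expect_lte(diff(range(cnt)), 1L)
  ## the pH gradient runs along the major axis, so region means are ordered
  expect_true(all(diff(ph$regionPH) > 0) || all(diff(ph$regionPH) < 0))
})

test_that("noiseless spectra tables give a perfect full-band refit", {
  ## the pH rule involves 12 bands; extra latent variables let PLS span
  ## that subspace exactly inside the 151 correlated bands
  tab <- generateSpectraTable(12, noiseSd = 0, seed = 86L)
  X <- spectraMatrix(tab); y <- pHRef(tab)
  fit <- fitPLSR(X, y, 30L)
  expect_gt(computeMetrics(y, predict(fit, X))$R2, 1 - 1e-6)
})

test_that("the preset generating rule is recovered coefficient-for-coefficient", {
  tab <- generateSpectraTable(33, noiseSd = 0, seed = 87L)
  truth <- presetReducedModel()
  bands <- bandOfWavelength(spectralGrid(tab), wavelengths(truth))
  X <- spectraMatrix(tab)[, bands]
  fit <- fitPLSR(X, pHRef(tab), 12L)
  expect_lt(max(abs(regressionCoefficients(fit) -
                      regressionCoefficients(truth)) /
                  abs(regressionCoefficients(truth))), 1e-4)
  expect_equal(intercept(fit), intercept(truth), tolerance = 1e-4)
})

test_that("more response noise does not reduce cross-validated error", {
  wl <- presetFeatureWavelengths()
  err <- sapply(c(0.05, 0.1, 0.2, 0.4), function(sd) {
    mean(sapply(1:5, function(rep) {
      tab <- generateSpectraTable(12, noiseSd = sd, seed = 880L + rep)
      bands <- bandOfWavelength(spectralGrid(tab), wl)
      crossValidate(spectraMatrix(tab)[, bands], pHRef(tab), 6L,
                    scheme = "kfold", k = 5L, seed = rep)$RMSECV
    }))
  })
  expect_true(all(diff(err) > 0))
})

test_that("simulated CCD responses honour their noise specification", {
  d <- generateCCD()
  y0 <- generateRSMResponses(presetSurface(), d, 0)
  expect_equal(y0, evaluateSurface(presetSurface(), uncodedMatrix(d)))
  y1 <- generateRSMResponses(presetSurface(), d, noiseSd = 0.2, seed = 89L)
  expect_identical(y1,
                   generateRSMResponses(presetSurface(), d, noiseSd = 0.2,
                                        seed = 89L))
  yc <- y1[d@pointType == "center"]
  expect_gt(sum((yc - mean(yc))^2), 0)
})
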