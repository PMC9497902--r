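test_that("the default CCD has the published structure", {
  d <- generateCCD()
  C <- codedMatrix(d)
  expect_equal(nrow(C), 32L)                      # 16 + 10 + 6
  expect_equal(sum(d@pointType == "factorial"), 16L)
  expect_equal(sum(d@pointType == "axial"), 10L)
  expect_equal(sum(d@pointType == "center"), 6L)
  ## defining relation on the factorial core
  fac <- C[d@pointType == "factorial", ]
  expect_equal(fac[, 5], fac[, 1] * fac[, 2] * fac[, 3] * fac[, 4])
  ## balance and factorial orthogonality
  expect_equal(unname(colSums(C)), rep(0, 5))
  expect_equal(unname(crossprod(fac)), diag(16, 5))
  ## axial rows have a single +/- alpha coordinate
  ax <- C[d@pointType == "axial", ]
  expect_true(all(rowSums(ax != 0) == 1L))
  expect_true(all(abs(ax[ax != 0]) == 2))
})

test_that("uncoded axial levels match the affine coding", {
  d <- generateCCD()
  U <- uncodedMatrix(d)
  ## lactic acid at coded +alpha is 22.50 mL/kg NaCl
  expect_true(any(abs(U[, 4] - 22.50) < 1e-9))
  expect_true(any(abs(U[, 5] - 105) < 1e-9))     # time at +alpha
  f5 <- presetFactors()[[5]]
  expect_equal(codeTransform(f5, 1, "to_uncoded"), 90)
  expect_equal(codeTransform(f5, 0, "to_uncoded"), 75)
  cs <- seq(-2, 2, by = 0.5)
  expect_equal(codeTransform(f5, codeTransform(f5, cs, "to_uncoded"),
                             "to_coded"), cs, tolerance = 1e-12)
})

test_that("run order shuffling is seeded and structure-preserving", {
  a <- generateCCD(seed = 5L); b <- generateCCD(seed = 5L)
  expect_identical(codedMatrix(a), codedMatrix(b))
  c2 <- generateCCD(seed = 6L)
  expect_false(identical(codedMatrix(a), codedMatrix(c2)))
  expect_equal(nrow(codedMatrix(c2)), 32L)
  expect_error(generateCCD(presetFactors()[1:3]), "5 factors")
})

test_that("the published treatment table obeys the defining relation", {
  tab <- publishedDesignTable()
  expect_equal(nrow(tab), 32L)
  Cc <- as.matrix(tab[, c("c1", "c2", "c3", "c4", "c5")])
  fac <- Cc[rowSums(abs(Cc) == 1) == 5, ]
  expect_equal(nrow(fac), 16L)
  expect_equal(fac[, 5], fac[, 1] * fac[, 2] * fac[, 3] * fac[, 4],
               ignore_attr = TRUE)
  ## lactic acid and time columns agree with exact affine coding everywhere
  f <- presetFactors()
  expect_equal(tab$X4, codeTransform(f[[4]], Cc[, 4], "to_uncoded"),
               tolerance = 1e-9)
  expect_equal(tab$X5, codeTransform(f[[5]], Cc[, 5], "to_uncoded"),
               tolerance = 1e-9)
})

test_that("noiseless surface fits recover the generating coefficients", {
  d <- generateCCD(seed = 61L)
  for (s in 71:90) {
    truth <- randomSurface(s)
    y <- generateRSMResponses(truth, d, 0)
    fit <- fitQuadraticSurface(d, y)
    betaT <- c(truth@beta0, truth@linear, truth@quadratic,
               truth@interaction)
    betaF <- c(fit@beta0, fit@linear, fit@quadratic, fit@interaction)
    expect_lt(max(abs(betaF - betaT) / pmax(abs(betaT), 1e-3)), 1e-6)
  }
})

test_that("coefficient error shrinks monotonically with the noise level", {
  d <- generateCCD(seed = 62L)
  truth <- randomSurface(99)
  betaT <- c(truth@beta0, truth@linear, truth@quadratic, truth@interaction)
  errs <- sapply(c(1e-2, 1e-4, 1e-6), function(sg) {
    y <- generateRSMResponses(truth, d, noiseSd = sg, seed = 63L)
    fit <- fitQuadraticSurface(d, y)
    max(abs(c(fit@beta0, fit@linear, fit@quadratic, fit@interaction) -
              betaT))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("constant responses collapse to an intercept-only surface", {
  d <- generateCCD()
  fit <- fitQuadraticSurface(d, rep(5.5, 32))
  expect_equal(fit@beta0, 5.5, tolerance = 1e-8)
  expect_lt(max(abs(c(fit@linear, fit@quadratic, fit@interaction))), 1e-8)
})

test_that("ANOVA df partition matches the 32-run design", {
  d <- generateCCD(seed = 64L)
  y <- generateRSMResponses(randomSurface(1), d, noiseSd = 0.3, seed = 65L)
  a <- anovaQuadratic(d, y)
  dfOf <- function(src) a$df[a$source == src]
  expect_equal(dfOf("Model"), 20L)
  expect_equal(dfOf("Linear"), 5L)
  expect_equal(dfOf("Square"), 5L)
  expect_equal(dfOf("2-Way Interaction"), 10L)
  expect_equal(dfOf("Error"), 11L)
  expect_equal(dfOf("Lack of Fit"), 6L)
  expect_equal(dfOf("Pure Error"), 5L)
  expect_equal(dfOf("Total"), 31L)
  ## SS(Error) = SS(LoF) + SS(PE)
  expect_equal(a$adj_SS[a$source == "Error"],
               a$adj_SS[a$source == "Lack of Fit"] +
                 a$adj_SS[a$source == "Pure Error"], tolerance = 1e-9)
})

test_that("ANOVA df identities hold for any centre-replicate count", {
  for (nc in 2:8) {
    d <- generateCCD(nCenter = nc)
    n <- 16L + 10L + nc
    y <- generateRSMResponses(randomSurface(nc), d, noiseSd = 0.2,
                              seed = nc)
    a <- anovaQuadratic(d, y)
    dfOf <- function(src) a$df[a$source == src]
    expect_equal(dfOf("Total"), n - 1L)
    expect_equal(dfOf("Error"), dfOf("Total") - dfOf("Model"))
    expect_equal(dfOf("Pure Error"), nc - 1L)
    expect_equal(dfOf("Lack of Fit"), dfOf("Error") - dfOf("Pure Error"))
  }
})

test_that("noiseless responses leave no residual error", {
  d <- generateCCD()
  y <- generateRSMResponses(presetSurface(), d, 0)
  a <- anovaQuadratic(d, y)
  expect_lt(a$adj_SS[a$source == "Error"], 1e-12)
})

test_that("pure error equals the direct centre-replicate accumulation", {
  d <- generateCCD()
  y <- generateRSMResponses(presetSurface(), d, noiseSd = 0.25, seed = 66L)
  a <- anovaQuadratic(d, y)
  yc <- y[d@pointType == "center"]
  expect_equal(a$adj_SS[a$source == "Pure Error"],
               sum((yc - mean(yc))^2), tolerance = 1e-10)
  expect_gt(a$adj_SS[a$source == "Pure Error"], 0)
})

test_that("a design without replicates omits lack of fit with a warning", {
  d <- generateCCD(nCenter = 1L)
  y <- generateRSMResponses(randomSurface(7), d, noiseSd = 0.2, seed = 67L)
  expect_warning(a <- anovaQuadratic(d, y), "replicated")
  expect_false("Lack of Fit" %in% a$source)
})

test_that("surface evaluation matches printed worked examples", {
  s <- presetSurface()
  expect_equal(evaluateSurface(s, rep(0, 5)), 59.0)
  expect_equal(evaluateSurface(s, c(1, 0, 0, 0, 0)), 59.0 + 1.52 - 0.052,
               tolerance = 1e-12)
  ## single-interaction surface is symmetric in its two factors
  si <- quadraticSurface(0, setNames(rep(0, 5), paste0("X", 1:5)),
                         setNames(rep(0, 5), paste0("X", 1:5)),
                         setNames(c(1, rep(0, 9)),
                                  names(presetSurface()@interaction)))
  expect_equal(evaluateSurface(si, c(2, 3, 0, 0, 0)), 6)
  expect_equal(evaluateSurface(si, c(3, 2, 0, 0, 0)), 6)
})

test_that("contour grids agree with pointwise evaluation", {
  s <- presetSurface()
  hold <- c(X2 = 1.78, X4 = 19.5, X5 = 75)
  cg <- contourGrid(s, c("X1", "X3"), hold, gridN = 11L)
  expect_true(all(is.finite(cg$z)))
  for (idx in list(c(1, 1), c(5, 7), c(11, 11))) {
    x <- c(cg$x[idx[1]], hold["X2"], cg$y[idx[2]], hold["X4"], hold["X5"])
    expect_equal(cg$z[idx[1], idx[2]],
                 evaluateSurface(s, unname(x)), tolerance = 1e-12)
  }
  flat <- quadraticSurface(2, setNames(rep(0, 5), paste0("X", 1:5)),
                           setNames(rep(0, 5), paste0("X", 1:5)),
                           setNames(rep(0, 10),
                                    names(presetSurface()@interaction)))
  cgFlat <- contourGrid(flat, c("X1", "X3"), hold, gridN = 5L)
  expect_equal(unname(range(cgFlat$z)), c(2, 2))
  expect_error(contourGrid(s, c("X1", "X3"), c(X1 = 1, X4 = 1, X5 = 1)),
               "overlap")
})

test_that("surfaces round-trip through JSON", {
  s <- presetSurface()
  path <- tempfile(fileext = ".json")
  writeSurfaceJSON(s, path)
  back <- readSurfaceJSON(path)
  expect_equal(back@beta0, 59.0)
  expect_equal(back@interaction, s@interaction)
  expect_equal(evaluateSurface(back, c(1, 2, 0.3, 19, 80)),
               evaluateSurface(s, c(1, 2, 0.3, 19, 80)), tolerance = 1e-12)
})
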