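test_that("snv standardizes each spectrum with the n-1 convention", {
  x <- withr::with_seed(1, runif(151, 0.1, 0.9))
  out <- snv(x)
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(sd(out), 1, tolerance = 1e-12)
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(snv(3 * x + 2), out, tolerance = 1e-12)  # affine invariance
  expect_equal(snv(snv(x)), snv(x), tolerance = 1e-10)  # idempotent
  expect_error(snv(rep(1, 10)), "zero variance")
})

test_that("msc removes affine scatter against the reference", {
  ref <- withr::with_seed(2, runif(50, 0.2, 0.8))
  expect_equal(msc(ref, ref), ref, tolerance = 1e-12)
  expect_equal(msc(2 * ref + 3, ref), ref, tolerance = 1e-12)
  X <- withr::with_seed(3, {
    t(sapply(1:6, function(i) runif(1, 0.5, 2) * ref + runif(1, -0.2, 0.2) +
               rnorm(50, 0, 0.01)))
  })
  once <- msc(X, ref)
  expect_equal(msc(once, ref), once, tolerance = 1e-10)  # idempotent
  ## the set-mean default never changes the reference itself
  Xr <- rbind(X, ref)
  expect_equal(msc(Xr, colMeans(Xr))[7, ],
               msc(ref, colMeans(Xr)), tolerance = 1e-12)
  expect_error(msc(rep(5, 50), ref + 100 - ref), "constant reference")
})

test_that("area normalization yields unit absolute area", {
  x <- withr::with_seed(4, rnorm(100))
  expect_equal(sum(abs(normalizeArea(x))), 1, tolerance = 1e-12)
  expect_equal(normalizeArea(5 * abs(x)), normalizeArea(abs(x)),
               tolerance = 1e-12)  # scale invariance
  expect_equal(normalizeArea(c(1, 3)), c(0.25, 0.75))
  expect_equal(normalizeArea(normalizeArea(x)), normalizeArea(x),
               tolerance = 1e-10)
  expect_error(normalizeArea(rep(0, 5)), "zero")
})

test_that("Savitzky-Golay derivatives reproduce analytic slopes", {
  i <- 1:60
  expect_equal(sgDerivative(rep(3.7, 60), 1), rep(0, 60), tolerance = 1e-10)
  lin <- 2.5 + 0.31 * i
  d1 <- sgDerivative(lin, 1)
  expect_equal(d1, rep(0.31, 60), tolerance = 1e-9)  # slope per band step
  d2 <- sgDerivative(lin, 2)
  expect_equal(d2[4:57], rep(0, 54), tolerance = 1e-9)
  expect_error(sgDerivative(1:5, 1), "window")

  ## linearity
  x <- withr::with_seed(5, rnorm(60)); y <- withr::with_seed(6, rnorm(60))
  expect_equal(sgDerivative(2 * x - 3 * y, 1),
               2 * sgDerivative(x, 1) - 3 * sgDerivative(y, 1),
               tolerance = 1e-10)
  expect_equal(sgDerivative(2 * x - 3 * y, 2),
               2 * sgDerivative(x, 2) - 3 * sgDerivative(y, 2),
               tolerance = 1e-10)
})

test_that("chain strings parse case-insensitively with + composition", {
  ch <- pretreatmentChain("normalization + 1ST Derivative")
  expect_equal(ch@steps, c("normalization", "first_derivative"))
  expect_equal(chainLabel(ch), "Normalization + 1st Derivative")
  expect_equal(pretreatmentChain("Raw")@steps, character(0))
  expect_error(pretreatmentChain("Raw + detrend"), "unknown")
})

test_that("the empty chain is the identity and order matters", {
  tab <- generateSpectraTable(4, noiseSd = 0, seed = 7)
  raw <- applyChain(tab, pretreatmentChain("Raw"))
  expect_equal(spectraMatrix(raw), spectraMatrix(tab))

  x <- spectraMatrix(tab)[1, , drop = FALSE]
  a <- applyChain(x, pretreatmentChain("Normalization + 1st Derivative"))
  b <- applyChain(x, pretreatmentChain("1st Derivative + Normalization"))
  expect_gt(max(abs(a - b)), 1e-6)
})

test_that("all 20 domain x treatment configurations run without error", {
  tab <- generateSpectraTable(4, noiseSd = 0, seed = 8)
  tabA <- replaceSpectra(tab, toAbsorbance(spectraMatrix(tab)),
                         domain = "absorbance")
  expect_length(tableChains(), 10L)
  for (dom in c("reflectance", "absorbance")) {
    src <- if (dom == "reflectance") tab else tabA
    for (ch in tableChains()) {
      out <- applyChain(src, pretreatmentChain(ch, dom))
      expect_true(all(is.finite(spectraMatrix(out))),
                  info = paste(dom, ch))
    }
  }
})

test_that("chain domain must match the table domain", {
  tab <- generateSpectraTable(3, noiseSd = 0, seed = 9)
  expect_error(applyChain(tab, pretreatmentChain("SNV", "absorbance")),
               "domain")
})

test_that("the MSC reference is learned on calibration rows only", {
  tab <- generateSpectraTable(6, noiseSd = 0, seed = 10)
  M <- spectraMatrix(tab)
  cal <- 1:20
  out <- applyChain(M, pretreatmentChain("MSC"), calibrationRows = cal)
  oracle <- msc(M, reference = colMeans(M[cal, ]))
  expect_equal(out, oracle, tolerance = 1e-12)
  outAll <- applyChain(M, pretreatmentChain("MSC"))
  expect_gt(max(abs(out - outAll)), 0)
})
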