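## Published reference artifacts shipped as presets: the 12-wavelength
## reduced pH calibration, the uncoded quadratic response surface for the
## casing-modification study, and its five design factors. These are data
## (printed model coefficients), not quantities the package re-derives.

#' Published 12-wavelength reduced pH model
#'
#' The reduced multispectral calibration for sausage pH: an intercept of
#' 5.335 and one coefficient per feature wavelength, applied to reflectance.
#' Shipped as a preset so prediction maps can be produced without refitting.
#'
#' @return A [LinearSpectralModel-class] (reflectance domain).
#' @examples
#' evaluateLinearModel(presetReducedModel(), rep(0, 12))  # 5.335
#' @export
presetReducedModel <- function() {
  linearSpectralModel(
    intercept = 5.335,
    wavelengthsNm = c(365, 385, 405, 475, 525, 580, 640, 725, 875, 915,
                      1005, 1060),
    coefficients = c(7.243, -0.060, 7.461, -4.098, 3.594, 4.443, -5.920,
                     -4.083, -3.246, 4.495, 3.520, -9.730),
    domain = "reflectance")
}

#' @describeIn presetReducedModel the preset's feature wavelengths (nm).
#' @export
presetFeatureWavelengths <- function() {
  c(365, 385, 405, 475, 525, 580, 640, 725, 875, 915, 1005, 1060)
}

#' Published quadratic response surface for sausage pH
#'
#' The fitted second-order polynomial (uncoded units) relating pH to the
#' five casing-modification factors: soy lecithin (X1, \% w/w), soy oil
#' (X2, \% w/w), orange extracts (X3, \% w/w), lactic acid (X4, mL/kg NaCl)
#' and treatment time (X5, min).
#'
#' @return A [QuadraticSurface-class] with the 21 published coefficients.
#' @examples
#' evaluateSurface(presetSurface(), c(0, 0, 0, 0, 0))  # 59.0
#' @export
presetSurface <- function() {
  quadraticSurface(
    beta0 = 59.0,
    linear = c(X1 = 1.52, X2 = -9.07, X3 = -8.40, X4 = -3.84, X5 = -0.252),
    quadratic = c(X1 = -0.052, X2 = 0.426, X3 = 7.82, X4 = 0.0635,
                  X5 = 0.0007),
    interaction = c("X1:X2" = 0.0110, "X1:X3" = -3.27, "X1:X4" = -0.016,
                    "X1:X5" = -0.0035, "X2:X3" = 2.07, "X2:X4" = 0.272,
                    "X2:X5" = 0.0216, "X3:X4" = 1.00, "X3:X5" = -0.1109,
                    "X4:X5" = 0.0086))
}

#' The five casing-modification design factors
#'
#' Centre/half-range codings of the five factors of the central composite
#' design: soy lecithin 3.16 +/- 1.045 \% w/w, soy oil 1.78 +/- 0.60 \% w/w,
#' orange extracts 0.26 +/- 0.14 \% w/w, lactic acid 19.50 +/- 1.50 mL/kg
#' NaCl, treatment time 75 +/- 15 min (the time applies identically to both
#' soaking stages, so it is one factor).
#'
#' @return list of five [FactorSpec-class] objects.
#' @export
presetFactors <- function() {
  list(factorSpec("X1", 3.16, 1.045, "% w/w soy lecithin"),
       factorSpec("X2", 1.78, 0.60, "% w/w soy oil"),
       factorSpec("X3", 0.26, 0.14, "% w/w orange extracts"),
       factorSpec("X4", 19.50, 1.50, "mL/kg NaCl lactic acid"),
       factorSpec("X5", 75, 15, "min treatment time"))
}

#' Verbatim treatment table of the casing-modification study
#'
#' The 32 treatment combinations as printed (uncoded values plus coded
#' levels), shipped as a plain-text fixture. A few printed uncoded values
#' disagree with exact affine coding by rounding (X1 and X2 axial points,
#' X3 low axial printed as 0.00) -- the fixture preserves the printed values
#' verbatim; [generateCCD()] uses exact coding.
#'
#' @return data.frame with columns treatment, X1..X5 (uncoded) and
#'   c1..c5 (coded levels).
#' @export
publishedDesignTable <- function() {
  path <- system.file("extdata", "casing_ccd_treatments.csv",
                      package = "hyperpH", mustWork = TRUE)
  utils::read.csv(path)
}
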