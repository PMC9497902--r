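#' Select feature wavelengths from a PLSR coefficient profile
#'
#' Candidate wavelengths are the local extrema (peaks and valleys) of the
#' collapsed regression-coefficient vector b: interior bands where the first
#' difference of b strictly changes sign. Candidates are ranked by |b| and
#' kept greedily subject to a minimum pairwise separation, then truncated to
#' the \code{k} strongest and returned in ascending wavelength order. If
#' fewer than \code{k} extrema exist, all found are returned with a warning.
#'
#' @param model a [PLSRModel-class] fitted on all bands of \code{grid}.
#' @param grid the [WavelengthGrid-class] of the model columns.
#' @param k number of wavelengths to keep.
#' @param minSeparationBands minimum index distance between kept wavelengths.
#' @return numeric vector of wavelengths (nm), ascending.
#' @seealso [presetFeatureWavelengths()] for the published 12-wavelength set.
#' @export
selectFeatureWavelengths <- function(model, grid, k = 12L,
                                     minSeparationBands = 2L) {
  stopifnot(is(model, "PLSRModel"), is(grid, "WavelengthGrid"))
  b <- model@coef
  if (length(b) != grid@nBands)
    stopf("model has %d coefficients but the grid has %d bands",
          length(b), grid@nBands)
  d <- diff(b)
  s <- sign(d)
  ## interior band i (2..p-1) is an extremum when the slope strictly flips
  cand <- which(s[-length(s)] * s[-1] < 0) + 1L
  if (!length(cand)) {
    warning("no interior extrema in the coefficient profile; returning none")
    return(numeric(0))
  }
  cand <- cand[order(-abs(b[cand]), cand)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= minSeparationBands))
      kept <- c(kept, i)
    if (length(kept) >= k) break
  }
  if (length(kept) < k)
    warning(sprintf("only %d extrema available after separation, %d requested",
                    length(kept), k))
  sort(wavelengthOfBand(grid, sort(kept)))
}

#' Construct an explicit linear spectral model
#'
#' @param intercept intercept (pH units).
#' @param wavelengthsNm wavelengths of the terms (nm); stored sorted.
#' @param coefficients one coefficient per wavelength.
#' @param domain spectral domain the model accepts.
#' @return A [LinearSpectralModel-class].
#' @export
linearSpectralModel <- function(intercept, wavelengthsNm, coefficients,
                                domain = "reflectance") {
  o <- order(wavelengthsNm)
  new("LinearSpectralModel", intercept = as.numeric(intercept),
      wavelengthsNm = as.numeric(wavelengthsNm[o]),
      coefficients = as.numeric(coefficients[o]), domain = domain)
}

#' @describeIn linearSpectralModel term coefficients.
#' @param object a [LinearSpectralModel-class].
#' @export
setMethod("regressionCoefficients", "LinearSpectralModel",
          function(object) object@coefficients)

#' @describeIn linearSpectralModel model intercept.
#' @export
setMethod("intercept", "LinearSpectralModel", function(object) object@intercept)

#' @describeIn linearSpectralModel term wavelengths (nm).
#' @param x a [LinearSpectralModel-class].
#' @param ... unused.
#' @export
setMethod("wavelengths", "LinearSpectralModel",
          function(x, ...) x@wavelengthsNm)

setMethod("show", "LinearSpectralModel", function(object) {
  cat("LinearSpectralModel:", formulaString(object), "\n")
})

#' Evaluate a linear spectral model
#'
#' Predicted pH is the intercept plus the dot product of the coefficients
#' with the reflectance at each model wavelength.
#'
#' @param model a [LinearSpectralModel-class].
#' @param reflectances numeric vector with one reflectance per model term,
#'   or an n x k matrix of such rows.
#' @return predicted pH (scalar or vector).
#' @examples
#' m <- presetReducedModel()
#' evaluateLinearModel(m, rep(0, 12))  # the intercept, 5.335
#' @export
evaluateLinearModel <- function(model, reflectances) {
  stopifnot(is(model, "LinearSpectralModel"))
  k <- length(model@coefficients)
  if (is.matrix(reflectances)) {
    if (ncol(reflectances) != k)
      stopf("expected %d reflectances per row, got %d", k, ncol(reflectances))
    return(as.numeric(model@intercept + reflectances %*% model@coefficients))
  }
  if (length(reflectances) != k)
    stopf("expected %d reflectances, got %d", k, length(reflectances))
  model@intercept + sum(model@coefficients * reflectances)
}

#' Human-readable formula for a linear spectral model
#'
#' @param model a [LinearSpectralModel-class].
#' @return a string like
#'   \code{"pH = 5.335 + 7.243 L365 - 0.060 L385 ..."}.
#' @export
formulaString <- function(model) {
  stopifnot(is(model, "LinearSpectralModel"))
  terms <- sprintf("%s %.3f L%g",
                   ifelse(model@coefficients < 0, "-", "+"),
                   abs(model@coefficients), model@wavelengthsNm)
  paste("pH =", format(model@intercept), paste(terms, collapse = " "))
}

#' Refit a reduced model on selected wavelengths
#'
#' Restricts the spectra to the feature wavelengths, applies the chain to
#' the reduced spectra (as a multispectral instrument would record them),
#' refits PLSR on the calibration rows and reports the six-number metric
#' record. For the empty (raw) chain the fit is also collapsed to an
#' explicit [LinearSpectralModel-class]; chains that transform each spectrum
#' nonlinearly in its band values have no such collapsed form and return
#' \code{NULL} there.
#'
#' @param set a [SpectraSet-class].
#' @param wavelengthsNm feature wavelengths; must be distinct and on-grid.
#' @param split calibration/prediction indices
#'   ([splitCalibrationPrediction()]).
#' @param nLatent latent variables (capped at the reduced band count).
#' @param chain optional chain applied to the reduced spectra.
#' @param cvScheme cross-validation scheme.
#' @return list with \code{plsr} ([PLSRModel-class]), \code{linear}
#'   ([LinearSpectralModel-class] or NULL) and \code{metrics} (one-row
#'   data.frame as in [chainMetrics()]).
#' @export
buildReducedModel <- function(set, wavelengthsNm, split, nLatent,
                              chain = NULL, cvScheme = "loo") {
  stopifnot(is(set, "SpectraSet"))
  if (anyDuplicated(wavelengthsNm)) stopf("duplicate feature wavelengths")
  grid <- spectralGrid(set)
  bands <- bandOfWavelength(grid, wavelengthsNm)
  sub <- spectraMatrix(set)[, bands, drop = FALSE]
  y <- pHRef(set)
  if (is.null(chain)) {
    chain <- new("PretreatmentChain", steps = character(0),
                 domain = if (spectralDomain(set) == "absorbance")
                   "absorbance" else "reflectance")
  } else if (is.character(chain)) {
    chain <- pretreatmentChain(chain, spectralDomain(set))
  }
  cal <- split$calibration; prd <- split$prediction
  M <- if (length(chain@steps))
    applyChain(sub, chain, calibrationRows = cal) else sub
  nl <- min(nLatent, length(bands), length(cal) - 1L)
  fit <- fitPLSR(M[cal, , drop = FALSE], y[cal], nl,
                 wavelengthsNm = sort(wavelengthsNm),
                 chain = chainLabel(chain))
  mc <- computeMetrics(y[cal], predict(fit, M[cal, , drop = FALSE]))
  mp <- computeMetrics(y[prd], predict(fit, M[prd, , drop = FALSE]))
  cv <- crossValidate(sub[cal, , drop = FALSE], y[cal], nl, scheme = cvScheme,
                      chain = if (length(chain@steps)) chain else NULL)
  metrics <- data.frame(domain = spectralDomain(set),
                        treatment = chainLabel(chain), n_latent = nl,
                        Rc2 = mc$R2, RMSEC = mc$RMSE, Rp2 = mp$R2,
                        RMSEP = mp$RMSE, Rcv2 = cv$R2cv, RMSECV = cv$RMSECV,
                        stringsAsFactors = FALSE)
  linear <- if (!length(chain@steps)) {
    o <- order(wavelengthsNm)
    linearSpectralModel(fit@b0, wavelengthsNm[o], fit@coef[o],
                        domain = if (spectralDomain(set) == "absorbance")
                          "absorbance" else "reflectance")
  } else NULL
  list(plsr = fit, linear = linear, metrics = metrics)
}

#' Fraction of wavelengths removed by a reduction
#'
#' @param nFull full band count.
#' @param nReduced reduced band count.
#' @return percentage of wavelengths removed, rounded to the nearest
#'   percent (151 to 12 bands gives 92).
#' @export
reductionPercent <- function(nFull, nReduced) {
  round(100 * (1 - nReduced / nFull))
}

#' Serialize / read a linear spectral model as JSON
#'
#' @param model a [LinearSpectralModel-class].
#' @param path JSON path.
#' @return \code{readLinearModelJSON}: a [LinearSpectralModel-class].
#' @export
writeLinearModelJSON <- function(model, path) {
  stopifnot(is(model, "LinearSpectralModel"))
  obj <- list(type = "LinearSpectralModel", intercept = model@intercept,
              wavelengths_nm = model@wavelengthsNm,
              coefficients = model@coefficients, domain = model@domain,
              formula = formulaString(model))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLinearModelJSON
#' @export
readLinearModelJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "LinearSpectralModel"))
    stopf("not a LinearSpectralModel JSON file")
  linearSpectralModel(obj$intercept, obj$wavelengths_nm, obj$coefficients,
                      domain = obj$domain)
}
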