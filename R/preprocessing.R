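## Spectral pretreatment operators. All operators accept a single spectrum
## (numeric vector) or a set of spectra as an observations x bands matrix and
## act per spectrum.

.asRows <- function(x) {
  if (is.matrix(x)) list(m = x, vec = FALSE)
  else list(m = matrix(x, nrow = 1L), vec = TRUE)
}
.unRows <- function(m, vec) if (vec) as.numeric(m[1L, ]) else m

#' Standard normal variate
#'
#' Centres each spectrum and scales it to unit standard deviation (sample,
#' n-1 convention), removing per-spectrum additive offset and multiplicative
#' scatter.
#'
#' @param x spectrum (vector) or observations x bands matrix.
#' @return same shape; each spectrum has mean 0 and sd 1.
#' @export
snv <- function(x) {
  a <- .asRows(x)
  mu <- rowMeans(a$m)
  s <- apply(a$m, 1L, stats::sd)
  if (any(s <= 0 | !is.finite(s)))
    stopf("snv: zero variance in spectrum %s",
          paste(utils::head(which(s <= 0 | !is.finite(s)), 3), collapse = ", "))
  .unRows((a$m - mu) / s, a$vec)
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed on the reference spectrum by ordinary least
#' squares, \eqn{x \approx a + b\,\mathrm{ref}}, and corrected to
#' \eqn{(x - a)/b}. The reference defaults to the mean spectrum of the set
#' it is applied to; in a calibration/prediction workflow pass the
#' calibration-set mean so prediction rows reuse the frozen reference.
#'
#' @param x spectrum (vector) or observations x bands matrix.
#' @param reference reference spectrum; default \code{colMeans} of \code{x}.
#' @return corrected spectra, same shape as \code{x}.
#' @export
msc <- function(x, reference = NULL) {
  a <- .asRows(x)
  if (is.null(reference)) {
    if (a$vec) stopf("msc on a single spectrum needs an explicit reference")
    reference <- colMeans(a$m)
  }
  stopifnot(length(reference) == ncol(a$m))
  rc <- reference - mean(reference)
  denom <- sum(rc * rc)
  if (denom <= 0) stopf("msc: constant reference spectrum")
  out <- a$m
  for (i in seq_len(nrow(a$m))) {
    xi <- a$m[i, ]
    b <- sum((xi - mean(xi)) * rc) / denom
    if (abs(b) < 1e-12)
      stopf("msc: spectrum %d has no multiplicative relation to the reference (b ~ 0)", i)
    aa <- mean(xi) - b * mean(reference)
    out[i, ] <- (xi - aa) / b
  }
  .unRows(out, a$vec)
}

#' Area normalization
#'
#' Scales each spectrum to unit absolute area, \eqn{x / \sum_j |x_j|}, so
#' spectra share an equal area under the curve.
#'
#' @param x spectrum (vector) or observations x bands matrix.
#' @return same shape; each spectrum has \eqn{\sum |x| = 1}.
#' @export
normalizeArea <- function(x) {
  a <- .asRows(x)
  area <- rowSums(abs(a$m))
  if (any(area <= 0)) stopf("normalizeArea: zero spectrum")
  .unRows(a$m / area, a$vec)
}

#' Savitzky-Golay derivative
#'
#' Same-length first or second derivative of each spectrum via a
#' Savitzky-Golay filter (default window 7; polynomial order 2 for the first
#' derivative, 3 for the second), with the filter's polynomial edge handling.
#' Derivatives are per band index (multiply by 1/step to express per nm).
#'
#' @param x spectrum (vector) or observations x bands matrix.
#' @param order derivative order, 1 or 2.
#' @param window odd filter window length (bands).
#' @param polyOrder fitting polynomial order; default 2 for \code{order = 1},
#'   3 for \code{order = 2}.
#' @return same shape as \code{x}.
#' @export
sgDerivative <- function(x, order = 1L, window = 7L, polyOrder = NULL) {
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stopf("order must be 1 or 2")
  if (is.null(polyOrder)) polyOrder <- if (order == 1L) 2L else 3L
  a <- .asRows(x)
  if (ncol(a$m) < window)
    stopf("spectrum length %d shorter than the %d-band filter window",
          ncol(a$m), window)
  out <- t(apply(a$m, 1L, function(v)
    signal::sgolayfilt(v, p = polyOrder, n = window, m = order)))
  .unRows(out, a$vec)
}

## ---- pretreatment chains ------------------------------------------------

.CHAIN_ALIASES <- c(
  "raw" = "",
  "1st derivative" = "first_derivative",
  "first derivative" = "first_derivative",
  "2nd derivative" = "second_derivative",
  "second derivative" = "second_derivative",
  "msc" = "msc",
  "snv" = "snv",
  "normalization" = "normalization",
  "normalisation" = "normalization")

#' Parse a pretreatment chain specification
#'
#' Chain strings use "+" for left-to-right composition and are parsed
#' case-insensitively, e.g. \code{"Normalization + 1st Derivative"},
#' \code{"MSC"}, \code{"SNV"}, or \code{"Raw"} (the empty chain).
#'
#' @param spec chain string, or character vector of canonical step names.
#' @param domain spectral domain the chain operates on.
#' @return A [PretreatmentChain-class].
#' @export
pretreatmentChain <- function(spec, domain = c("reflectance", "absorbance")) {
  domain <- match.arg(domain)
  if (length(spec) == 1L && (grepl("+", spec, fixed = TRUE) ||
                             tolower(spec) %in% names(.CHAIN_ALIASES))) {
    parts <- tolower(trimws(strsplit(spec, "+", fixed = TRUE)[[1]]))
    unknown <- setdiff(parts, names(.CHAIN_ALIASES))
    if (length(unknown))
      stopf("unknown pretreatment(s): %s", paste(unknown, collapse = ", "))
    steps <- .CHAIN_ALIASES[parts]
    steps <- unname(steps[nzchar(steps)])
  } else {
    steps <- as.character(spec)
  }
  new("PretreatmentChain", steps = steps, domain = domain)
}

#' @describeIn pretreatmentChain the ten chain labels of the standard
#'   comparison (raw plus nine single/composed pretreatments).
#' @export
tableChains <- function() {
  c("Raw", "1st Derivative", "2nd Derivative", "MSC", "SNV", "Normalization",
    "Normalization + 1st Derivative", "1st Derivative + Normalization",
    "Normalization + 2nd Derivative", "2nd Derivative + Normalization")
}

#' @describeIn pretreatmentChain printable label of a chain.
#' @param chain a [PretreatmentChain-class].
#' @export
chainLabel <- function(chain) {
  stopifnot(is(chain, "PretreatmentChain"))
  if (!length(chain@steps)) return("Raw")
  pretty <- c(first_derivative = "1st Derivative",
              second_derivative = "2nd Derivative", msc = "MSC", snv = "SNV",
              normalization = "Normalization")
  paste(pretty[chain@steps], collapse = " + ")
}

setMethod("show", "PretreatmentChain", function(object) {
  cat(sprintf("PretreatmentChain [%s]: %s\n", object@domain,
              chainLabel(object)))
})

#' Apply a pretreatment chain
#'
#' Applies the chain's steps left to right. Steps that learn statistics from
#' a reference set (the MSC reference spectrum) learn them on
#' \code{calibrationRows} only -- after any preceding steps -- and freeze
#' them for all other rows, so prediction rows never leak into the reference.
#'
#' @param x a [SpectraSet-class] or observations x bands matrix.
#' @param chain a [PretreatmentChain-class] (its domain must match the
#'   set's domain) or a chain string.
#' @param calibrationRows integer indices of the calibration rows; default
#'   all rows.
#' @param window,polyOrder1,polyOrder2 Savitzky-Golay settings forwarded to
#'   [sgDerivative()].
#' @return same class as \code{x}, with pretreated spectra (domain tag
#'   \code{"pretreated"} for a non-empty chain on a SpectraSet).
#' @export
applyChain <- function(x, chain, calibrationRows = NULL, window = 7L,
                       polyOrder1 = 2L, polyOrder2 = 3L) {
  isSet <- is(x, "SpectraSet")
  if (is.character(chain))
    chain <- pretreatmentChain(chain, if (isSet && spectralDomain(x) ==
                                          "absorbance") "absorbance"
                               else "reflectance")
  stopifnot(is(chain, "PretreatmentChain"))
  m <- if (isSet) spectraMatrix(x) else as.matrix(x)
  if (isSet && spectralDomain(x) != chain@domain)
    stopf("chain domain '%s' does not match table domain '%s'",
          chain@domain, spectralDomain(x))
  if (is.null(calibrationRows)) calibrationRows <- seq_len(nrow(m))
  for (step in chain@steps) {
    m <- switch(step,
      first_derivative = sgDerivative(m, 1L, window, polyOrder1),
      second_derivative = sgDerivative(m, 2L, window, polyOrder2),
      msc = msc(m, reference = colMeans(m[calibrationRows, , drop = FALSE])),
      snv = snv(m),
      normalization = normalizeArea(m),
      stopf("unknown pretreatment step '%s'", step))
  }
  if (!isSet) return(m)
  replaceSpectra(x, m, domain = if (length(chain@steps)) "pretreated"
                 else spectralDomain(x))
}
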