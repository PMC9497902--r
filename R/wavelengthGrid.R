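#' Construct a uniform wavelength grid
#'
#' Builds the spectral axis from inclusive endpoints and a step. The default
#' arguments give the camera grid used throughout: 350--1100 nm at 5 nm,
#' i.e. 151 bands with band 70 at 695 nm.
#'
#' @param startNm first wavelength (nm).
#' @param stopNm last wavelength (nm); must exceed \code{startNm} and the
#'   range must be an exact multiple of \code{stepNm}.
#' @param stepNm band spacing (nm).
#' @return A [WavelengthGrid-class].
#' @examples
#' g <- wavelengthGrid(350, 1100, 5)
#' nBands(g)              # 151
#' wavelengthOfBand(g, 70) # 695
#' @export
wavelengthGrid <- function(startNm = 350, stopNm = 1100, stepNm = 5) {
  if (stopNm <= startNm) stopf("stopNm (%g) must exceed startNm (%g)",
                               stopNm, startNm)
  if (stepNm <= 0) stopf("stepNm must be positive")
  span <- stopNm - startNm
  k <- span / stepNm
  if (!nearlyInteger(k))
    stopf("range %g nm is not divisible by step %g nm (remainder %g nm)",
          span, stepNm, span - floor(k) * stepNm)
  new("WavelengthGrid", startNm = as.numeric(startNm),
      stepNm = as.numeric(stepNm), nBands = as.integer(round(k)) + 1L)
}

#' @describeIn wavelengthGrid all wavelengths of a grid, in band order.
#' @param x a [WavelengthGrid-class] (or object carrying one).
#' @param ... unused.
#' @export
setMethod("wavelengths", "WavelengthGrid", function(x, ...) {
  x@startNm + (seq_len(x@nBands) - 1L) * x@stepNm
})

#' @describeIn wavelengthGrid number of bands.
#' @export
setMethod("nBands", "WavelengthGrid", function(x) x@nBands)

#' @describeIn wavelengthGrid wavelength (nm) of a 1-based band index.
#' @param band 1-based band index (vectorised).
#' @export
setMethod("wavelengthOfBand", "WavelengthGrid", function(x, band) {
  band <- as.integer(band)
  if (any(band < 1L | band > x@nBands))
    stopf("band index out of range 1..%d", x@nBands)
  x@startNm + (band - 1L) * x@stepNm
})

#' @describeIn wavelengthGrid 1-based band index of an on-grid wavelength.
#' @param nm wavelength in nm; must lie exactly on the grid.
#' @export
setMethod("bandOfWavelength", "WavelengthGrid", function(x, nm) {
  idx <- (nm - x@startNm) / x@stepNm + 1
  if (any(!nearlyInteger(idx)) || any(idx < 1 - 1e-8) ||
      any(idx > x@nBands + 1e-8))
    stopf("wavelength(s) %s not on the grid",
          paste(nm[!nearlyInteger(idx) | idx < 1 | idx > x@nBands],
                collapse = ", "))
  as.integer(round(idx))
})

setMethod("show", "WavelengthGrid", function(object) {
  cat(sprintf("WavelengthGrid: %g-%g nm, step %g nm, %d bands\n",
              object@startNm,
              object@startNm + (object@nBands - 1L) * object@stepNm,
              object@stepNm, object@nBands))
})
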