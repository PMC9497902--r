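#' @include AllClasses.R
NULL

#' @export
setGeneric("wavelengths", function(x, ...) standardGeneric("wavelengths"))

#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @export
setGeneric("wavelengthOfBand", function(x, band) standardGeneric("wavelengthOfBand"))

#' @export
setGeneric("bandOfWavelength", function(x, nm) standardGeneric("bandOfWavelength"))

#' @export
setGeneric("spectralDomain", function(x) standardGeneric("spectralDomain"))

#' @export
setGeneric("spectralGrid", function(x) standardGeneric("spectralGrid"))

#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))

#' @export
setGeneric("toAbsorbance", function(x, ...) standardGeneric("toAbsorbance"))

#' @export
setGeneric("toReflectance", function(x, ...) standardGeneric("toReflectance"))

#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @export
setGeneric("regressionCoefficients", function(object) standardGeneric("regressionCoefficients"))

#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))
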