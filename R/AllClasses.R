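## Central S4 classes. Spatial convention throughout: images are row x col
## matrices, hypercubes row x col x band arrays. Band indexing is 1-based:
## band i sits at startNm + (i - 1) * stepNm.

#' Uniform wavelength grid
#'
#' Describes the spectral axis of a hypercube or spectra table: a uniformly
#' spaced set of wavelengths. Band indexing is 1-based, so band \code{i} lies
#' at \code{startNm + (i - 1) * stepNm}; for the default visible/NIR camera
#' grid (350--1100 nm in 5 nm steps, 151 bands) band 70 is 695 nm.
#'
#' @slot startNm numeric(1), wavelength of band 1 in nm.
#' @slot stepNm numeric(1), band spacing in nm (> 0).
#' @slot nBands integer(1), number of bands (>= 2).
#'
#' @seealso [wavelengthGrid()]
#' @export
setClass("WavelengthGrid",
         representation(startNm = "numeric", stepNm = "numeric",
                        nBands = "integer"),
         validity = function(object) {
           msg <- NULL
           if (length(object@startNm) != 1L || !is.finite(object@startNm))
             msg <- c(msg, "startNm must be a single finite number")
           if (length(object@stepNm) != 1L || !is.finite(object@stepNm) ||
               object@stepNm <= 0)
             msg <- c(msg, "stepNm must be a single positive number")
           if (length(object@nBands) != 1L || object@nBands < 2L)
             msg <- c(msg, "nBands must be >= 2")
           if (is.null(msg)) TRUE else msg
         })

#' Hyperspectral data cube
#'
#' A 3-D array of per-pixel spectra (rows x cols x bands) with its wavelength
#' grid and a domain tag recording whether values are raw camera counts,
#' calibrated reflectance, or absorbance.
#'
#' @slot values numeric array, rows x cols x bands; all values finite,
#'   nonnegative when the domain is reflectance.
#' @slot grid a [WavelengthGrid-class]; its band count must equal
#'   \code{dim(values)[3]}.
#' @slot domain one of \code{"raw"}, \code{"reflectance"},
#'   \code{"absorbance"}.
#'
#' @seealso [hypercube()], [calibrateReflectance()], [toAbsorbance()]
#' @export
setClass("Hypercube",
         representation(values = "array", grid = "WavelengthGrid",
                        domain = "character"),
         validity = function(object) {
           msg <- NULL
           d <- dim(object@values)
           if (length(d) != 3L)
             msg <- c(msg, "values must be a 3-D array (rows x cols x bands)")
           else if (d[3] != object@grid@nBands)
             msg <- c(msg, sprintf(
               "third dimension (%d) must equal grid band count (%d)",
               d[3], object@grid@nBands))
           if (!all(is.finite(object@values)))
             msg <- c(msg, "values must all be finite")
           if (!object@domain %in% c("raw", "reflectance", "absorbance"))
             msg <- c(msg, "domain must be raw, reflectance or absorbance")
           if (identical(object@domain, "reflectance") &&
               any(object@values < 0))
             msg <- c(msg, "reflectance values must be nonnegative")
           if (is.null(msg)) TRUE else msg
         })

#' Foreground mask from threshold segmentation
#'
#' @slot mask logical matrix, TRUE on sausage pixels.
#' @slot bandIndex 1-based band the threshold was applied at.
#' @slot threshold reflectance threshold (strict ">").
#' @export
setClass("SegmentationMask",
         representation(mask = "matrix", bandIndex = "integer",
                        threshold = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (!is.logical(object@mask))
             msg <- c(msg, "mask must be a logical matrix")
           if (!any(object@mask))
             msg <- c(msg, "mask must contain at least one foreground pixel")
           if (is.null(msg)) TRUE else msg
         })

#' Equal-area region labels over a mask
#'
#' @slot labels integer matrix: 0 background, 1..k regions.
#' @slot k number of regions.
#' @export
setClass("RegionLabels",
         representation(labels = "matrix", k = "integer"),
         validity = function(object) {
           msg <- NULL
           lab <- object@labels
           if (!is.numeric(lab) && !is.integer(lab))
             msg <- c(msg, "labels must be an integer matrix")
           present <- sort(unique(as.integer(lab[lab > 0])))
           if (length(present) && !identical(present, seq_len(object@k)))
             msg <- c(msg, "region labels must be exactly 1..k")
           cnt <- tabulate(as.integer(lab[lab > 0]), nbins = object@k)
           if (object@k > 0L && (max(cnt) - min(cnt)) > 1L)
             msg <- c(msg, "region pixel counts must differ by at most 1")
           if (is.null(msg)) TRUE else msg
         })

#' Region mean spectra with reference pH
#'
#' A \linkS4class{SummarizedExperiment} holding one mean spectrum per
#' (sample, region) observation: the assay \code{"spectra"} is bands x
#' observations, \code{rowData} carries the wavelength of each band, and
#' \code{colData} carries \code{sample_code}, \code{region_id} and
#' \code{pH_ref}. The wavelength grid and spectral domain live in
#' \code{metadata}.
#'
#' @seealso [spectraSet()], [extractMeanSpectra()], [spectraMatrix()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment",
         validity = function(object) {
           msg <- NULL
           cd <- SummarizedExperiment::colData(object)
           need <- c("sample_code", "region_id", "pH_ref")
           miss <- setdiff(need, colnames(cd))
           if (length(miss))
             return(paste("missing colData columns:",
                          paste(miss, collapse = ", ")))
           if (any(cd$pH_ref <= 0 | cd$pH_ref >= 14))
             msg <- c(msg, "pH_ref must lie in (0, 14)")
           key <- paste(cd$sample_code, cd$region_id)
           if (anyDuplicated(key))
             msg <- c(msg, "sample_code x region_id must be unique")
           md <- S4Vectors::metadata(object)
           if (is.null(md$grid) || !is(md$grid, "WavelengthGrid"))
             msg <- c(msg, "metadata$grid must be a WavelengthGrid")
           else if (md$grid@nBands != nrow(object))
             msg <- c(msg, "grid band count must equal assay row count")
           if (is.null(md$domain) ||
               !md$domain %in% c("reflectance", "absorbance", "pretreated"))
             msg <- c(msg, "metadata$domain must be reflectance, absorbance or pretreated")
           if (is.null(msg)) TRUE else msg
         })

#' Ordered spectral pretreatment chain
#'
#' An ordered list of pretreatment steps applied left to right, together with
#' the spectral domain (reflectance or absorbance) the chain operates on.
#' Step names: \code{first_derivative}, \code{second_derivative}, \code{msc},
#' \code{snv}, \code{normalization}. The empty chain is the raw treatment.
#'
#' @slot steps character vector of step names (possibly empty).
#' @slot domain \code{"reflectance"} or \code{"absorbance"}.
#' @seealso [pretreatmentChain()], [applyChain()]
#' @export
setClass("PretreatmentChain",
         representation(steps = "character", domain = "character"),
         validity = function(object) {
           ok <- c("first_derivative", "second_derivative", "msc", "snv",
                   "normalization")
           bad <- setdiff(object@steps, ok)
           msg <- NULL
           if (length(bad))
             msg <- c(msg, paste("unknown pretreatment step(s):",
                                 paste(bad, collapse = ", ")))
           if (!object@domain %in% c("reflectance", "absorbance"))
             msg <- c(msg, "domain must be reflectance or absorbance")
           if (is.null(msg)) TRUE else msg
         })

#' Partial least squares regression model (NIPALS)
#'
#' Latent-variable regression of a single response on band spectra, fitted by
#' NIPALS with deflation on the mean-centred data. Besides the per-component
#' weights, loadings and scores, the model stores its collapsed form: an
#' intercept \code{b0} and a coefficient vector \code{b} over bands, so that
#' predictions are \code{b0 + X \%*\% b}.
#'
#' @slot nLatent number of latent variables.
#' @slot xMean,yMean centring vectors.
#' @slot weights p x A weight matrix W.
#' @slot xLoadings p x A loading matrix P.
#' @slot yLoadings length-A response loadings q.
#' @slot scores n x A training score matrix T (mutually orthogonal columns).
#' @slot coef collapsed band coefficient vector b.
#' @slot b0 collapsed intercept.
#' @slot wavelengthsNm wavelengths of the model columns (NA when unitless).
#' @slot chain label of the pretreatment chain the model was fitted on.
#' @seealso [fitPLSR()]
#' @export
setClass("PLSRModel",
         representation(nLatent = "integer", xMean = "numeric",
                        yMean = "numeric", weights = "matrix",
                        xLoadings = "matrix", yLoadings = "numeric",
                        scores = "matrix", coef = "numeric", b0 = "numeric",
                        wavelengthsNm = "numeric", chain = "character"))

#' Explicit linear spectral model (intercept + per-wavelength coefficients)
#'
#' The collapsed form of a reduced calibration: predicted pH is the intercept
#' plus the dot product of the coefficients with the reflectance at each
#' listed wavelength. Wavelengths are strictly increasing.
#'
#' @slot intercept numeric(1), pH units.
#' @slot wavelengthsNm strictly increasing wavelengths (nm).
#' @slot coefficients one coefficient per wavelength (pH per unit reflectance).
#' @slot domain spectral domain the model accepts (\code{"reflectance"}).
#' @seealso [linearSpectralModel()], [evaluateLinearModel()],
#'   [presetReducedModel()]
#' @export
setClass("LinearSpectralModel",
         representation(intercept = "numeric", wavelengthsNm = "numeric",
                        coefficients = "numeric", domain = "character"),
         validity = function(object) {
           msg <- NULL
           if (length(object@wavelengthsNm) != length(object@coefficients))
             msg <- c(msg, "one coefficient per wavelength required")
           if (length(object@wavelengthsNm) > 1L &&
               any(diff(object@wavelengthsNm) <= 0))
             msg <- c(msg, "wavelengths must be strictly increasing")
           if (is.null(msg)) TRUE else msg
         })

#' Design factor: centre/half-range coding
#'
#' @slot name factor name (e.g. "X1").
#' @slot center uncoded value at coded level 0.
#' @slot halfrange uncoded units per coded unit (> 0).
#' @slot units text units.
#' @seealso [factorSpec()], [codeTransform()]
#' @export
setClass("FactorSpec",
         representation(name = "character", center = "numeric",
                        halfrange = "numeric", units = "character"),
         validity = function(object) {
           if (object@halfrange <= 0) "halfrange must be > 0" else TRUE
         })

#' Central composite design
#'
#' A five-factor CCD: half-fraction 2^(5-1) factorial core with defining
#' relation X5 = X1 X2 X3 X4, two axial runs per factor at distance alpha,
#' and replicated centre runs.
#'
#' @slot factors list of five [FactorSpec-class] objects.
#' @slot alpha coded axial distance.
#' @slot nCenter number of centre replicates.
#' @slot coded runs x 5 matrix of coded levels, in run order.
#' @slot pointType "factorial", "axial" or "center" per run.
#' @seealso [generateCCD()], [uncodedMatrix()]
#' @export
setClass("CCDDesign",
         representation(factors = "list", alpha = "numeric",
                        nCenter = "integer", coded = "matrix",
                        pointType = "character"),
         validity = function(object) {
           msg <- NULL
           if (ncol(object@coded) != length(object@factors))
             msg <- c(msg, "coded matrix must have one column per factor")
           if (length(object@pointType) != nrow(object@coded))
             msg <- c(msg, "pointType must have one entry per run")
           if (is.null(msg)) TRUE else msg
         })

#' Quadratic response surface in uncoded units
#'
#' Full second-order polynomial in five factors: intercept, 5 linear, 5 pure
#' quadratic and 10 two-way interaction coefficients (21 in total).
#'
#' @slot beta0 intercept.
#' @slot linear named length-5 vector of linear coefficients.
#' @slot quadratic named length-5 vector of squared-term coefficients.
#' @slot interaction named length-10 vector ("X1:X2", ...) of interaction
#'   coefficients.
#' @seealso [quadraticSurface()], [evaluateSurface()], [presetSurface()]
#' @export
setClass("QuadraticSurface",
         representation(beta0 = "numeric", linear = "numeric",
                        quadratic = "numeric", interaction = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (length(object@linear) != 5L || length(object@quadratic) != 5L)
             msg <- c(msg, "linear and quadratic must each have 5 coefficients")
           if (length(object@interaction) != 10L)
             msg <- c(msg, "interaction must have 10 coefficients")
           if (is.null(msg)) TRUE else msg
         })

#' Pixel-wise pH prediction map
#'
#' @slot values numeric matrix of predicted pH, NA outside the mask.
#' @slot mask logical foreground matrix, same shape.
#' @slot scale length-2 display range (min, max).
#' @seealso [predictMap()], [renderMap()]
#' @export
setClass("PredictionMap",
         representation(values = "matrix", mask = "matrix",
                        scale = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (!identical(dim(object@values), dim(object@mask)))
             msg <- c(msg, "values and mask shapes must agree")
           if (any(is.na(object@values[object@mask])))
             msg <- c(msg, "values must be finite on the mask")
           if (!all(is.na(object@values[!object@mask])))
             msg <- c(msg, "values must be NA off the mask")
           if (is.null(msg)) TRUE else msg
         })

#' Synthetic sausage phantom specification
#'
#' Parameters of the synthetic hypercube generator: an elliptical sausage on
#' a dark background, a smooth reflectance baseline with Gaussian absorption
#' features whose depths are coupled to a latent pH field, per-pixel
#' multiplicative/additive scatter, and i.i.d. noise. The generator is a pure
#' function of the spec and its seed.
#'
#' @slot nrow,ncol image size in pixels.
#' @slot grid wavelength grid of the cube.
#' @slot background background reflectance (must stay below the segmentation
#'   threshold at 695 nm).
#' @slot baselineKnots 2-column matrix (wavelength nm, reflectance) of spline
#'   knots for the sausage baseline.
#' @slot features data.frame with columns center, width (nm), baseDepth and
#'   slope (fractional depth per pH unit) of each absorption feature.
#' @slot pH length-1 (constant) or length-2 (linear gradient along the major
#'   axis) latent pH.
#' @slot gainSd,offsetSd per-pixel multiplicative and additive scatter sd.
#' @slot noiseSd per-pixel, per-band noise sd.
#' @slot seed integer seed.
#' @seealso [phantomSpec()], [generatePhantomHypercube()]
#' @export
setClass("PhantomSpec",
         representation(nrow = "integer", ncol = "integer",
                        grid = "WavelengthGrid", background = "numeric",
                        baselineKnots = "matrix", features = "data.frame",
                        pH = "numeric", gainSd = "numeric",
                        offsetSd = "numeric", noiseSd = "numeric",
                        seed = "integer"))
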