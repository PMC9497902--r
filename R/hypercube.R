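#' Construct a hypercube
#'
#' @param values rows x cols x bands numeric array.
#' @param grid matching [WavelengthGrid-class].
#' @param domain \code{"raw"}, \code{"reflectance"} or \code{"absorbance"}.
#' @return A [Hypercube-class].
#' @export
hypercube <- function(values, grid, domain = c("raw", "reflectance",
                                               "absorbance")) {
  domain <- match.arg(domain)
  new("Hypercube", values = values, grid = grid, domain = domain)
}

#' @describeIn hypercube the raw value array.
#' @param x a [Hypercube-class].
#' @export
setMethod("cubeValues", "Hypercube", function(x) x@values)

#' @describeIn hypercube the wavelength grid.
#' @export
setMethod("spectralGrid", "Hypercube", function(x) x@grid)

#' @describeIn hypercube the domain tag.
#' @export
setMethod("spectralDomain", "Hypercube", function(x) x@domain)

#' @export
setMethod("dim", "Hypercube", function(x) dim(x@values))

#' @describeIn hypercube wavelengths of the cube's grid.
#' @param ... unused.
#' @export
setMethod("wavelengths", "Hypercube", function(x, ...) wavelengths(x@grid))

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@values)
  cat(sprintf("Hypercube: %d x %d pixels, %d bands [%s]\n",
              d[1], d[2], d[3], object@domain))
  show(object@grid)
})

#' Dark/white reflectance calibration
#'
#' Converts a raw cube to relative reflectance with the standard two-point
#' calibration \eqn{R = (R_r - R_d) / (R_w - R_d)}, where \eqn{R_d} is the
#' dark reference (0\% reflectance, lens capped) and \eqn{R_w} the white
#' reference (100\%). References may be full cubes of the same shape or
#' per-band vectors, which broadcast across pixels.
#'
#' @param raw a [Hypercube-class] with domain \code{"raw"}.
#' @param dark,white dark and white references: arrays shaped like
#'   \code{cubeValues(raw)} or numeric vectors of length \code{nBands}.
#' @return A reflectance-domain [Hypercube-class].
#' @examples
#' g <- wavelengthGrid(0, 10, 5)
#' raw <- hypercube(array(50, c(2, 2, 3)), g, "raw")
#' r <- calibrateReflectance(raw, dark = rep(0, 3), white = rep(100, 3))
#' range(cubeValues(r))  # all 0.5
#' @export
calibrateReflectance <- function(raw, dark, white) {
  stopifnot(is(raw, "Hypercube"))
  if (raw@domain != "raw")
    stopf("calibrateReflectance expects a raw-domain cube, got '%s'",
          raw@domain)
  d <- dim(raw@values)
  expand <- function(ref, what) {
    if (is.array(ref) && length(dim(ref)) == 3L) {
      if (!identical(dim(ref), d))
        stopf("%s reference shape does not match the cube", what)
      ref
    } else if (is.numeric(ref) && is.null(dim(ref))) {
      if (length(ref) != d[3])
        stopf("%s reference vector must have one value per band (%d)",
              what, d[3])
      aperm(array(ref, c(d[3], d[1], d[2])), c(2, 3, 1))
    } else stopf("%s reference must be a cube-shaped array or per-band vector",
                 what)
  }
  darkA <- expand(dark, "dark")
  whiteA <- expand(white, "white")
  denom <- whiteA - darkA
  if (any(denom <= 0)) {
    bad <- which(apply(denom <= 0, 3, any))
    stopf("white - dark is not strictly positive (band %s)",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  vals <- (raw@values - darkA) / denom
  vals[vals < 0] <- 0  # sensor noise below the dark reference
  hypercube(vals, raw@grid, "reflectance")
}

.absorb <- function(v, clip, what) {
  if (any(v <= 0)) {
    if (!clip) {
      bad <- which(v <= 0)[1]
      stopf("nonpositive reflectance at %s %d; use clip = TRUE to floor at 1e-6",
            what, bad)
    }
    v[v < 1e-6] <- 1e-6
  }
  -log10(v)
}

#' Reflectance to absorbance and back
#'
#' Absorbance is \eqn{A = -\log_{10} R} (base-10 by convention). The inverse,
#' \code{toReflectance}, is \eqn{R = 10^{-A}}.
#'
#' @param x a reflectance [Hypercube-class], matrix or vector (for
#'   \code{toAbsorbance}); absorbance equivalent for \code{toReflectance}.
#' @param clip if TRUE, reflectance below 1e-6 is floored there instead of
#'   raising an error.
#' @param ... unused.
#' @return same shape as the input, with the domain tag flipped for cubes.
#' @examples
#' toAbsorbance(c(1, 0.1, 0.01))  # 0 1 2
#' @export
setMethod("toAbsorbance", "Hypercube", function(x, clip = FALSE, ...) {
  if (x@domain != "reflectance")
    stopf("toAbsorbance expects a reflectance cube, got '%s'", x@domain)
  hypercube(.absorb(x@values, clip, "flat index"), x@grid, "absorbance")
})

#' @rdname toAbsorbance
#' @export
setMethod("toAbsorbance", "numeric", function(x, clip = FALSE, ...) {
  .absorb(x, clip, "element")
})

#' @rdname toAbsorbance
#' @export
setMethod("toAbsorbance", "matrix", function(x, clip = FALSE, ...) {
  out <- .absorb(as.vector(x), clip, "flat index")
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname toAbsorbance
#' @export
setMethod("toReflectance", "Hypercube", function(x, ...) {
  if (x@domain != "absorbance")
    stopf("toReflectance expects an absorbance cube, got '%s'", x@domain)
  hypercube(10^(-x@values), x@grid, "reflectance")
})

#' @rdname toAbsorbance
#' @export
setMethod("toReflectance", "numeric", function(x, ...) 10^(-x))

#' @rdname toAbsorbance
#' @export
setMethod("toReflectance", "matrix", function(x, ...) 10^(-x))

#' Pull one pixel's spectrum
#'
#' @param cube a [Hypercube-class].
#' @param row,col pixel coordinates.
#' @return numeric vector over bands.
#' @export
pixelSpectrum <- function(cube, row, col) {
  stopifnot(is(cube, "Hypercube"))
  as.numeric(cube@values[row, col, ])
}
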