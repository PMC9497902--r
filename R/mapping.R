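#' Pixel-wise pH prediction map
#'
#' Unfolds the masked pixels of a reflectance cube into a (pixels x feature
#' wavelengths) matrix, applies the reduced linear model (intercept plus
#' coefficient per wavelength), and refolds the predictions into a 2-D image
#' with NA outside the mask.
#'
#' @param cube reflectance [Hypercube-class].
#' @param model a reflectance-domain [LinearSpectralModel-class] whose
#'   wavelengths all lie on the cube's grid.
#' @param mask a [SegmentationMask-class] or logical matrix matching the
#'   cube's spatial shape.
#' @param scale optional length-2 display range; default the range of the
#'   predicted values. A fixed range (e.g. \code{c(4.4, 6.5)}) makes maps of
#'   different sausages comparable.
#' @return A [PredictionMap-class].
#' @export
predictMap <- function(cube, model, mask, scale = NULL) {
  stopifnot(is(cube, "Hypercube"), is(model, "LinearSpectralModel"))
  if (cube@domain != "reflectance")
    stopf("predictMap expects a reflectance cube, got '%s'", cube@domain)
  if (model@domain != "reflectance")
    stopf("the reduced model is %s-domain; prediction maps use reflectance",
          model@domain)
  m <- if (is(mask, "SegmentationMask")) mask@mask else mask
  d <- dim(cube@values)
  if (!identical(dim(m), d[1:2])) stopf("mask shape does not match the cube")
  if (!any(m)) stopf("empty mask")
  bands <- bandOfWavelength(cube@grid, model@wavelengthsNm)
  idx <- which(m)
  flat <- matrix(cube@values, d[1] * d[2], d[3])
  unfolded <- flat[idx, bands, drop = FALSE]
  pred <- evaluateLinearModel(model, unfolded)
  values <- matrix(NA_real_, d[1], d[2])
  values[idx] <- pred
  if (is.null(scale)) scale <- range(pred)
  if (scale[1] >= scale[2]) scale <- scale + c(-0.5, 0.5)
  new("PredictionMap", values = values, mask = m,
      scale = as.numeric(scale))
}

#' @describeIn predictMap the predicted-pH matrix (NA off the mask).
#' @param x a [PredictionMap-class].
#' @export
mapValues <- function(x) {
  stopifnot(is(x, "PredictionMap"))
  x@values
}

setMethod("show", "PredictionMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("PredictionMap: %d x %d, %d masked pixels, pH %0.3f-%0.3f (scale %0.2f-%0.2f)\n",
              nrow(object@values), ncol(object@values), sum(object@mask),
              min(v), max(v), object@scale[1], object@scale[2]))
})

#' Render a prediction map as PNG
#'
#' Maps values linearly onto the palette over the map's display scale and
#' writes an RGBA PNG with background pixels transparent; a vertical colour
#' bar of the palette is appended on the right. Encoding is deterministic:
#' identical inputs give byte-identical files.
#'
#' @param map a [PredictionMap-class].
#' @param path output PNG path.
#' @param palette vector of colours; default 256-step viridis.
#' @param colorbarWidth width (pixels) of the appended colour bar; 0 to
#'   omit.
#' @return the path, invisibly.
#' @export
renderMap <- function(map, path,
                      palette = grDevices::hcl.colors(256, "viridis"),
                      colorbarWidth = 16L) {
  stopifnot(is(map, "PredictionMap"))
  lo <- map@scale[1]; hi <- map@scale[2]
  if (lo >= hi) stopf("display scale min must be below max")
  nr <- nrow(map@values); nc <- ncol(map@values)
  rgbPal <- grDevices::col2rgb(palette) / 255
  img <- array(0, c(nr, nc + ifelse(colorbarWidth > 0, colorbarWidth + 4L, 0L),
                    4L))
  frac <- (map@values - lo) / (hi - lo)
  frac[frac < 0] <- 0; frac[frac > 1] <- 1
  pix <- which(map@mask)
  ci <- 1L + as.integer(round(frac[pix] * (length(palette) - 1L)))
  rowIdx <- ((pix - 1L) %% nr) + 1L
  colIdx <- ((pix - 1L) %/% nr) + 1L
  for (ch in 1:3)
    img[cbind(rowIdx, colIdx, ch)] <- rgbPal[ch, ci]
  img[cbind(rowIdx, colIdx, 4L)] <- 1
  if (colorbarWidth > 0) {
    barIdx <- 1L + as.integer(round((nr - seq_len(nr)) / (nr - 1) *
                                    (length(palette) - 1L)))
    for (ch in 1:3)
      img[, nc + 4L + seq_len(colorbarWidth), ch] <-
        matrix(rgbPal[ch, barIdx], nr, colorbarWidth)
    img[, nc + 4L + seq_len(colorbarWidth), 4L] <- 1
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Simple three-band RGB composite of a cube
#'
#' @param cube reflectance [Hypercube-class].
#' @param wavelengthsNm length-3 wavelengths used as R, G, B channels.
#' @return rows x cols x 3 array in [0, 1].
#' @export
compositeRGB <- function(cube, wavelengthsNm = c(640, 550, 460)) {
  stopifnot(is(cube, "Hypercube"), length(wavelengthsNm) == 3L)
  bands <- bandOfWavelength(cube@grid, wavelengthsNm)
  img <- cube@values[, , bands, drop = FALSE]
  img[img > 1] <- 1; img[img < 0] <- 0
  img
}

#' Export a prediction map's value grid as CSV
#'
#' Background (no-data) pixels are written as the sentinel value
#' \code{-9999}.
#'
#' @param map a [PredictionMap-class].
#' @param path CSV path.
#' @param sentinel no-data value.
#' @return the path, invisibly.
#' @export
writeMapCSV <- function(map, path, sentinel = -9999) {
  v <- map@values
  v[is.na(v)] <- sentinel
  utils::write.table(v, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a mask or label image as PNG
#'
#' Grayscale PNG with labels scaled to 0..1 (mask: 0 background, 1
#' foreground; labels: r/k for region r).
#'
#' @param x a [SegmentationMask-class] or [RegionLabels-class].
#' @param path PNG path.
#' @return the path, invisibly.
#' @export
writeMaskPNG <- function(x, path) {
  img <- if (is(x, "SegmentationMask")) x@mask * 1
         else if (is(x, "RegionLabels")) x@labels / max(1L, x@k)
         else stopf("x must be a SegmentationMask or RegionLabels")
  png::writePNG(img, path)
  invisible(path)
}
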