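#' Threshold segmentation of the sausage foreground
#'
#' Pixels whose reflectance at \code{bandIndex} strictly exceeds
#' \code{threshold} are foreground; values equal to the threshold are
#' background. The defaults (band 70 = 695 nm, threshold 0.075) separate the
#' sausage from the dark backdrop. With \code{keepLargest = TRUE} only the
#' largest 4-connected component is retained, discarding speckle that clears
#' the threshold in the background.
#'
#' @param cube reflectance [Hypercube-class].
#' @param bandIndex 1-based band to threshold at.
#' @param threshold reflectance threshold (strict ">").
#' @param keepLargest keep only the largest 4-connected component.
#' @return A [SegmentationMask-class].
#' @export
segmentCube <- function(cube, bandIndex = 70L, threshold = 0.075,
                        keepLargest = TRUE) {
  stopifnot(is(cube, "Hypercube"))
  if (cube@domain != "reflectance")
    stopf("segmentCube expects a reflectance cube, got '%s'", cube@domain)
  bandIndex <- as.integer(bandIndex)
  if (bandIndex < 1L || bandIndex > cube@grid@nBands)
    stopf("bandIndex %d outside grid (1..%d)", bandIndex, cube@grid@nBands)
  plane <- cube@values[, , bandIndex]
  fg <- plane > threshold
  if (!any(fg)) stopf("no foreground pixels above %g at band %d",
                      threshold, bandIndex)
  if (keepLargest) {
    lab <- EBImage::bwlabel(fg)  # 4-connected labelling
    counts <- tabulate(as.integer(lab[lab > 0]))
    fg <- lab == which.max(counts)
  }
  new("SegmentationMask", mask = fg, bandIndex = bandIndex,
      threshold = threshold)
}

#' @describeIn segmentCube the logical mask matrix.
#' @param x a [SegmentationMask-class].
#' @export
setMethod("maskMatrix", "SegmentationMask", function(x) x@mask)

setMethod("show", "SegmentationMask", function(object) {
  cat(sprintf("SegmentationMask: %d / %d pixels foreground (band %d > %g)\n",
              sum(object@mask), length(object@mask), object@bandIndex,
              object@threshold))
})

#' Split a mask into k regions of equal area
#'
#' Mask pixels are projected onto the mask's major principal axis (the
#' leading eigenvector of the pixel-coordinate covariance) and cut into
#' \code{k} contiguous bins of equal size -- the digital analogue of slicing
#' a cylindrical sausage crosswise. When the pixel count is not divisible by
#' \code{k}, the earliest bins take the remainder, so bin sizes differ by at
#' most one pixel. Projection ties are broken by pixel index for determinism.
#'
#' @param mask a [SegmentationMask-class] or logical matrix.
#' @param k number of regions.
#' @return A [RegionLabels-class].
#' @export
splitRegions <- function(mask, k = 5L) {
  m <- if (is(mask, "SegmentationMask")) mask@mask else mask
  stopifnot(is.logical(m), is.matrix(m))
  k <- as.integer(k)
  if (k < 1L) stopf("k must be >= 1")
  idx <- which(m)
  n <- length(idx)
  if (n < k) stopf("mask has %d pixels, fewer than k = %d regions", n, k)
  labels <- matrix(0L, nrow(m), ncol(m))
  if (k == 1L) {
    labels[idx] <- 1L
    return(new("RegionLabels", labels = labels, k = 1L))
  }
  coords <- cbind(row(m)[idx], col(m)[idx])
  cc <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(cc) / max(1, n - 1), symmetric = TRUE)$vectors[, 1]
  proj <- as.numeric(cc %*% ev)
  ord <- order(proj, idx)  # ties broken by linear pixel index
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  labels[idx[ord]] <- rep(seq_len(k), times = sizes)
  new("RegionLabels", labels = labels, k = k)
}

#' @describeIn splitRegions the integer label matrix.
#' @param x a [RegionLabels-class].
#' @export
setMethod("labelMatrix", "RegionLabels", function(x) x@labels)

setMethod("show", "RegionLabels", function(object) {
  cnt <- tabulate(as.integer(object@labels[object@labels > 0]),
                  nbins = object@k)
  cat(sprintf("RegionLabels: %d regions, sizes %s\n", object@k,
              paste(cnt, collapse = ", ")))
})

#' Mean spectrum per region
#'
#' Averages the cube's per-pixel spectra over each labelled region and
#' assembles the region means, the sample code and the (sausage-level)
#' reference pH into a [SpectraSet-class].
#'
#' @param cube a [Hypercube-class] whose spatial shape matches the labels.
#' @param labels a [RegionLabels-class].
#' @param sampleCode sample code for this sausage.
#' @param pHRef reference pH shared by the sausage's regions.
#' @return A [SpectraSet-class] with one observation per region.
#' @export
extractMeanSpectra <- function(cube, labels, sampleCode, pHRef) {
  stopifnot(is(cube, "Hypercube"), is(labels, "RegionLabels"))
  d <- dim(cube@values)
  if (!identical(dim(labels@labels), d[1:2]))
    stopf("label image shape does not match the cube")
  k <- labels@k
  flatLab <- as.integer(labels@labels)
  mat <- matrix(cube@values, d[1] * d[2], d[3])
  means <- matrix(NA_real_, k, d[3])
  for (r in seq_len(k)) {
    sel <- flatLab == r
    if (!any(sel)) stopf("region %d is empty", r)
    means[r, ] <- colMeans(mat[sel, , drop = FALSE])
  }
  dom <- if (cube@domain == "absorbance") "absorbance" else "reflectance"
  spectraSet(means, cube@grid, rep(sampleCode, k), seq_len(k),
             rep(pHRef, k), domain = dom)
}
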