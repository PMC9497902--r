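## Synthetic phantoms with the statistical structure the analysis assumes:
## an elliptical "sausage" on a dark background, smooth reflectance
## baselines with heme-pigment (418/544/574/582 nm) and water (780/980 nm)
## absorption features whose depths are coupled to a latent pH, per-pixel
## multiplicative/additive scatter to exercise MSC/SNV, and i.i.d. noise.
## This is a fixture convention, not a chemical model: feature depths simply
## decrease linearly with pH as a proxy for pigment loss.

.defaultFeatures <- function() {
  data.frame(
    center = c(418, 544, 574, 582, 780, 980),
    width = c(12, 10, 8, 8, 35, 40),
    baseDepth = c(0.45, 0.30, 0.22, 0.25, 0.18, 0.30),
    slope = c(-0.06, -0.05, -0.04, -0.05, -0.02, -0.03))
}

.defaultBaselineKnots <- function() {
  cbind(nm = c(350, 450, 550, 650, 750, 900, 1100),
        r = c(0.18, 0.25, 0.34, 0.42, 0.50, 0.55, 0.52))
}

#' Specify a synthetic sausage phantom
#'
#' Defaults emulate the acquisition scene of the pipeline's target
#' instrument: a 350--1100 nm, 151-band grid; an elongated elliptical
#' sausage (about half the frame) on a background of reflectance 0.03, well
#' below the 0.075 segmentation threshold at 695 nm; heme and water
#' absorption features; pH in the observed 4.44--6.46 span; 5\%
#' multiplicative and 0.005 additive per-pixel scatter and 0.002 spectral
#' noise.
#'
#' @param nrow,ncol image size (pixels).
#' @param grid wavelength grid.
#' @param background background reflectance.
#' @param baselineKnots 2-column matrix (nm, reflectance) of baseline spline
#'   knots.
#' @param features data.frame (center, width, baseDepth, slope) of Gaussian
#'   absorption features; depth at pH is
#'   \code{baseDepth + slope * (pH - 5.45)}.
#' @param pH length-1 constant or length-2 gradient endpoints along the
#'   major (column) axis.
#' @param gainSd,offsetSd,noiseSd scatter and noise standard deviations.
#' @param seed integer seed; the generator is a pure function of spec+seed.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(nrow = 80L, ncol = 120L,
                        grid = wavelengthGrid(350, 1100, 5),
                        background = 0.03,
                        baselineKnots = .defaultBaselineKnots(),
                        features = .defaultFeatures(),
                        pH = 5.45, gainSd = 0.05, offsetSd = 0.005,
                        noiseSd = 0.002, seed = 1L) {
  new("PhantomSpec", nrow = as.integer(nrow), ncol = as.integer(ncol),
      grid = grid, background = as.numeric(background),
      baselineKnots = baselineKnots, features = features,
      pH = as.numeric(pH), gainSd = as.numeric(gainSd),
      offsetSd = as.numeric(offsetSd), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

## Pure sausage spectrum at a given pH (no scatter/noise).
.phantomSpectrum <- function(spec, pH) {
  wl <- wavelengths(spec@grid)
  base <- stats::spline(spec@baselineKnots[, 1], spec@baselineKnots[, 2],
                        xout = wl, method = "natural")$y
  r <- base
  for (i in seq_len(nrow(spec@features))) {
    f <- spec@features[i, ]
    depth <- f$baseDepth + f$slope * (pH - 5.45)
    depth <- min(max(depth, 0), 0.95)
    r <- r * (1 - depth * exp(-0.5 * ((wl - f$center) / f$width)^2))
  }
  r
}

#' Generate a phantom hypercube with ground truth
#'
#' Builds the reflectance cube
#' \code{baseline x prod(1 - depth(pH) gauss) x gain + offset + noise} on
#' sausage pixels and a flat noisy background elsewhere, plus the ground
#' truth the recovery tests compare against: the true ellipse mask, its
#' equal-area region labels, and the mean latent pH per region.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with \code{cube} ([Hypercube-class]), \code{mask} (logical
#'   matrix), \code{labels} ([RegionLabels-class]), \code{regionPH}
#'   (length-k vector) and \code{pixelPH} (matrix, NA off the sausage).
#' @export
generatePhantomHypercube <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  nr <- spec@nrow; nc <- spec@ncol
  wl <- wavelengths(spec@grid)
  band695 <- bandOfWavelength(spec@grid, 695)
  ## separability precheck at the segmentation band
  pHs <- range(spec@pH)
  minSausage <- min(.phantomSpectrum(spec, pHs[1])[band695],
                    .phantomSpectrum(spec, pHs[2])[band695])
  if (!(spec@background < 0.075 && minSausage > 0.075))
    stopf("spec violates the segmentation separability invariant at 695 nm (background %g, sausage %g)",
          spec@background, minSausage)
  ## elliptical sausage, elongated along columns
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  a <- 0.42 * nc; b <- 0.32 * nr
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- ((cols - cc) / a)^2 + ((rows - rc) / b)^2 <= 1
  if (!any(mask)) stopf("degenerate geometry: empty sausage")
  ## latent pH field: constant, or linear gradient along the column axis
  pixelPH <- matrix(NA_real_, nr, nc)
  if (length(spec@pH) == 1L) {
    pixelPH[mask] <- spec@pH
  } else {
    cr <- range(cols[mask])
    frac <- (cols[mask] - cr[1]) / max(1, diff(cr))
    pixelPH[mask] <- spec@pH[1] + frac * (spec@pH[2] - spec@pH[1])
  }
  nBand <- spec@grid@nBands
  vals <- withSeed(spec@seed, {
    v <- array(0, c(nr, nc, nBand))
    bg <- spec@background +
      stats::rnorm(sum(!mask) * nBand, 0, spec@noiseSd)
    v[rep(!mask, nBand)] <- bg
    idx <- which(mask)
    gain <- 1 + stats::rnorm(length(idx), 0, spec@gainSd)
    offset <- stats::rnorm(length(idx), 0, spec@offsetSd)
    uph <- pixelPH[idx]
    ## cache pure spectra per distinct pH value
    uu <- unique(uph)
    specCache <- vapply(uu, function(p) .phantomSpectrum(spec, p),
                        numeric(nBand))
    pure <- specCache[, match(uph, uu), drop = FALSE]  # bands x pixels
    noise <- matrix(stats::rnorm(length(idx) * nBand, 0, spec@noiseSd),
                    nrow = nBand)
    px <- pure * rep(gain, each = nBand) +
      rep(offset, each = nBand) + noise
    flat <- matrix(v, nr * nc, nBand)
    flat[idx, ] <- t(px)
    array(flat, c(nr, nc, nBand))
  })
  vals[vals < 1e-4] <- 1e-4
  vals[vals > 1.19] <- 1.19
  cube <- hypercube(vals, spec@grid, "reflectance")
  labels <- splitRegions(mask, 5L)
  regionPH <- vapply(seq_len(5L), function(r)
    mean(pixelPH[labels@labels == r]), numeric(1))
  list(cube = cube, mask = mask, labels = labels, regionPH = regionPH,
       pixelPH = pixelPH)
}

#' Generate a spectra table from a known linear pH rule
#'
#' Draws random smooth reflectance spectra (a gentle baseline plus random
#' Gaussian bumps) and assigns each observation the pH given by the true
#' linear model evaluated at its reflectances, plus optional Gaussian noise.
#' With zero noise a full-rank refit restricted to the model's wavelengths
#' recovers the generating coefficients exactly, which is what the recovery
#' tests assert.
#'
#' @param nSamples number of sausages; each contributes
#'   \code{regionsPerSample} observations.
#' @param trueModel the generating [LinearSpectralModel-class]
#'   (default [presetReducedModel()]).
#' @param noiseSd pH noise standard deviation.
#' @param grid wavelength grid of the spectra.
#' @param regionsPerSample observations per sample code.
#' @param seed integer seed.
#' @return A [SpectraSet-class] with \code{nSamples * regionsPerSample}
#'   observations.
#' @export
generateSpectraTable <- function(nSamples = 33L,
                                 trueModel = presetReducedModel(),
                                 noiseSd = 0,
                                 grid = wavelengthGrid(350, 1100, 5),
                                 regionsPerSample = 5L, seed = 1L) {
  nSamples <- as.integer(nSamples)
  if (nSamples < 2L) stopf("nSamples must be >= 2")
  n <- nSamples * as.integer(regionsPerSample)
  wl <- wavelengths(grid)
  M <- withSeed(seed, {
    t(vapply(seq_len(n), function(i) {
      r <- rep(0.40, length(wl)) + 0.05 * sin(wl / 180 + stats::runif(1, 0, 6))
      for (j in seq_len(10L)) {
        amp <- stats::rnorm(1, 0, 0.04)
        mu <- stats::runif(1, min(wl), max(wl))
        sg <- stats::runif(1, 20, 120)
        r <- r + amp * exp(-0.5 * ((wl - mu) / sg)^2)
      }
      pmin(pmax(r, 0.02), 0.98)
    }, numeric(length(wl))))
  })
  bands <- bandOfWavelength(grid, trueModel@wavelengthsNm)
  pH <- evaluateLinearModel(trueModel, M[, bands, drop = FALSE])
  if (noiseSd > 0)
    pH <- pH + withSeed(seed + 1L, stats::rnorm(n, 0, noiseSd))
  pH <- pmin(pmax(pH, 0.05), 13.95)
  spectraSet(M, grid,
             sampleCode = rep(sprintf("S%03d", seq_len(nSamples)),
                              each = regionsPerSample),
             regionId = rep(seq_len(regionsPerSample), nSamples),
             pHRef = pH, domain = "reflectance")
}

#' Simulate responses of a CCD experiment from a known surface
#'
#' @param surface the true [QuadraticSurface-class] (e.g.
#'   [presetSurface()]).
#' @param design a [CCDDesign-class].
#' @param noiseSd response noise standard deviation.
#' @param seed integer seed.
#' @return numeric response vector, one per run.
#' @export
generateRSMResponses <- function(surface, design, noiseSd = 0, seed = 1L) {
  stopifnot(is(surface, "QuadraticSurface"), is(design, "CCDDesign"))
  y <- evaluateSurface(surface, uncodedMatrix(design))
  if (noiseSd > 0)
    y <- y + withSeed(seed, stats::rnorm(length(y), 0, noiseSd))
  y
}
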