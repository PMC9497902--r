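#' Construct a SpectraSet
#'
#' @param spectra observations x bands numeric matrix (one mean spectrum per
#'   row), or bands x observations with \code{byRow = FALSE}.
#' @param grid the shared [WavelengthGrid-class].
#' @param sampleCode character vector of sample codes, one per observation.
#' @param regionId integer region ids (1..k), one per observation.
#' @param pHRef numeric reference pH, one per observation (a sausage-level
#'   value repeated across its regions).
#' @param domain spectral domain of the stored spectra.
#' @param byRow whether \code{spectra} rows are observations (default TRUE).
#' @return A [SpectraSet-class].
#' @export
spectraSet <- function(spectra, grid, sampleCode, regionId, pHRef,
                       domain = c("reflectance", "absorbance", "pretreated"),
                       byRow = TRUE) {
  domain <- match.arg(domain)
  m <- as.matrix(spectra)
  if (byRow) m <- t(m)
  if (nrow(m) != grid@nBands)
    stopf("spectra have %d bands but the grid has %d", nrow(m), grid@nBands)
  n <- ncol(m)
  stopifnot(length(sampleCode) == n, length(regionId) == n,
            length(pHRef) == n)
  wl <- wavelengths(grid)
  rownames(m) <- sprintf("w%04d", wl)
  colnames(m) <- paste0(sampleCode, "_r", regionId)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectra = m),
    rowData = S4Vectors::DataFrame(wavelength_nm = wl),
    colData = S4Vectors::DataFrame(sample_code = as.character(sampleCode),
                                   region_id = as.integer(regionId),
                                   pH_ref = as.numeric(pHRef)),
    metadata = list(grid = grid, domain = domain))
  new("SpectraSet", se)
}

#' SpectraSet accessors
#'
#' \code{spectraMatrix} returns the observations x bands matrix used by the
#' modelling functions; \code{pHRef}, \code{sampleCode} and \code{regionId}
#' return the per-observation annotations.
#'
#' @param x a [SpectraSet-class].
#' @return see description.
#' @export
spectraMatrix <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  t(SummarizedExperiment::assay(x, "spectra"))
}

#' @rdname spectraMatrix
#' @export
pHRef <- function(x) SummarizedExperiment::colData(x)$pH_ref

#' @rdname spectraMatrix
#' @export
sampleCode <- function(x) SummarizedExperiment::colData(x)$sample_code

#' @rdname spectraMatrix
#' @export
regionId <- function(x) SummarizedExperiment::colData(x)$region_id

#' @describeIn spectraMatrix the shared wavelength grid.
#' @param ... unused.
#' @export
setMethod("spectralGrid", "SpectraSet",
          function(x) S4Vectors::metadata(x)$grid)

#' @describeIn spectraMatrix the spectral domain tag.
#' @export
setMethod("spectralDomain", "SpectraSet",
          function(x) S4Vectors::metadata(x)$domain)

#' @describeIn spectraMatrix wavelengths of the shared grid.
#' @export
setMethod("wavelengths", "SpectraSet",
          function(x, ...) wavelengths(spectralGrid(x)))

#' Replace the spectra of a SpectraSet
#'
#' Returns a copy of \code{x} whose assay holds \code{m} (observations x
#' bands) and whose domain tag is updated; annotations are preserved.
#'
#' @param x a [SpectraSet-class].
#' @param m observations x bands matrix conforming to \code{x}.
#' @param domain new domain tag.
#' @return A [SpectraSet-class].
#' @export
replaceSpectra <- function(x, m, domain = spectralDomain(x)) {
  stopifnot(is(x, "SpectraSet"), nrow(m) == ncol(x),
            ncol(m) == nrow(x))
  out <- x
  mm <- t(m)
  dimnames(mm) <- dimnames(SummarizedExperiment::assay(x, "spectra"))
  SummarizedExperiment::assay(out, "spectra") <- mm
  S4Vectors::metadata(out)$domain <- domain
  out
}
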