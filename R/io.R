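## ENVI-style cube I/O: an ASCII .hdr alongside a raw binary file, BSQ or BIL
## interleave, IEEE little-endian, data type 4 (float32) or 5 (float64).
## No installed R package reads ENVI, so the (small) format support lives here.

#' Write / read an ENVI-style hypercube
#'
#' \code{writeENVI} writes \code{path} (raw binary) plus \code{path.hdr}
#' (ASCII header with samples/lines/bands, interleave, data type, byte order
#' and the wavelength list). \code{readENVI} reads the pair back, validates
#' the header wavelength list against the band count, and rebuilds the
#' uniform grid.
#'
#' @param cube a [Hypercube-class].
#' @param path data-file path; the header is written at \code{<path>.hdr}.
#' @param interleave \code{"bsq"} (band sequential) or \code{"bil"} (band
#'   interleaved by line).
#' @param dataType ENVI data type code: 4 (float32) or 5 (float64).
#' @return \code{writeENVI}: the data path, invisibly. \code{readENVI}: a
#'   [Hypercube-class].
#' @export
writeENVI <- function(cube, path, interleave = c("bsq", "bil"),
                      dataType = 5L) {
  stopifnot(is(cube, "Hypercube"))
  interleave <- match.arg(interleave)
  if (!dataType %in% c(4L, 5L)) stopf("dataType must be 4 or 5")
  d <- dim(cube@values)
  wl <- wavelengths(cube@grid)
  hdr <- c("ENVI",
           "description = {hyperpH hypercube}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", dataType),
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("domain = %s", cube@domain),
           "wavelength units = nm",
           paste0("wavelength = {", paste(format(wl, trim = TRUE),
                                          collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  v <- cube@values
  flat <- switch(interleave,
                 ## BSQ: sample fastest, then line, then band
                 bsq = as.vector(aperm(v, c(2, 1, 3))),
                 ## BIL: sample fastest, then band, then line
                 bil = as.vector(aperm(v, c(2, 3, 1))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(flat), con,
           size = if (dataType == 4L) 4L else 8L, endian = "little")
  invisible(path)
}

#' @rdname writeENVI
#' @export
readENVI <- function(path) {
  hdrPath <- paste0(path, ".hdr")
  if (!file.exists(hdrPath)) stopf("header not found: %s", hdrPath)
  lines <- readLines(hdrPath, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  getField <- function(name, required = TRUE) {
    m <- regmatches(txt, regexec(
      paste0("(?mi)^", name, "\\s*=\\s*([^\\{\\n][^\\n]*)$"), txt,
      perl = TRUE))[[1]]
    if (length(m) < 2) {
      if (required) stopf("header field '%s' missing", name)
      return(NA_character_)
    }
    trimws(m[2])
  }
  samples <- as.integer(getField("samples"))
  nlines <- as.integer(getField("lines"))
  bands <- as.integer(getField("bands"))
  dataType <- as.integer(getField("data type"))
  interleave <- tolower(getField("interleave"))
  byteOrder <- as.integer(getField("byte order"))
  domain <- getField("domain", required = FALSE)
  if (is.na(domain)) domain <- "raw"
  if (!dataType %in% c(4L, 5L)) stopf("unsupported data type %d", dataType)
  if (!interleave %in% c("bsq", "bil"))
    stopf("unsupported interleave '%s'", interleave)
  wm <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(wm) < 2) stopf("header wavelength list missing")
  wl <- as.numeric(strsplit(wm[2], ",")[[1]])
  if (length(wl) != bands)
    stopf("header lists %d wavelengths for %d bands", length(wl), bands)
  steps <- diff(wl)
  if (length(steps) && (max(steps) - min(steps)) > 1e-6)
    stopf("wavelength list is not uniformly spaced")
  n <- samples * nlines * bands
  con <- file(path, "rb")
  on.exit(close(con))
  flat <- readBin(con, what = "numeric",
                  size = if (dataType == 4L) 4L else 8L, n = n,
                  endian = if (byteOrder == 0L) "little" else "big")
  if (length(flat) != n)
    stopf("data file holds %d values, header implies %d", length(flat), n)
  v <- switch(interleave,
              bsq = aperm(array(flat, c(samples, nlines, bands)), c(2, 1, 3)),
              bil = aperm(array(flat, c(samples, bands, nlines)), c(3, 1, 2)))
  grid <- wavelengthGrid(wl[1], wl[length(wl)], steps[1])
  hypercube(v, grid, domain)
}

#' Write / read a spectra table as CSV
#'
#' Columns: \code{sample_code}, \code{region_id}, \code{pH_ref}, then one
#' column per band named \code{w0350}, \code{w0355}, ... (wavelength in nm).
#'
#' @param x a [SpectraSet-class].
#' @param path CSV path.
#' @param domain spectral domain to tag the read table with (the CSV itself
#'   is domain-agnostic).
#' @return \code{readSpectraTable}: a [SpectraSet-class].
#' @export
writeSpectraTable <- function(x, path) {
  stopifnot(is(x, "SpectraSet"))
  df <- data.frame(sample_code = sampleCode(x), region_id = regionId(x),
                   pH_ref = pHRef(x), check.names = FALSE)
  df <- cbind(df, as.data.frame(spectraMatrix(x)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraTable
#' @export
readSpectraTable <- function(path, domain = "reflectance") {
  df <- utils::read.csv(path, check.names = FALSE)
  wcols <- grep("^w[0-9]{4}$", colnames(df), value = TRUE)
  if (!length(wcols)) stopf("no wavelength columns (w0350 ...) found")
  wl <- as.numeric(sub("^w", "", wcols))
  o <- order(wl)
  wl <- wl[o]; wcols <- wcols[o]
  steps <- diff(wl)
  if (length(steps) && (max(steps) - min(steps)) > 1e-6)
    stopf("wavelength columns are not uniformly spaced")
  grid <- wavelengthGrid(wl[1], wl[length(wl)], steps[1])
  spectraSet(as.matrix(df[, wcols]), grid, df$sample_code, df$region_id,
             df$pH_ref, domain = domain)
}
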