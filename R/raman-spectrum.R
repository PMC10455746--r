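#' Construct a Raman spectrum
#'
#' The unit of all spectral operations: a strictly increasing wavenumber
#' axis with one intensity per grid point. Input in descending axis order
#' is sorted ascending (intensities reordered with the axis).
#'
#' @param wavenumber wavenumbers, 1/cm, length >= 2, no duplicates.
#' @param intensity intensities (counts), same length, finite.
#' @param meta free-form provenance list (sample id, culture condition,
#'   ground-truth band parameters for synthetic spectra, pipeline
#'   fingerprint).
#' @return object of class `raman_spectrum`: list with elements
#'   `wavenumber`, `intensity`, `meta`.
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list()) {
  if (!is.numeric(wavenumber) || !is.numeric(intensity))
    stop_field("wavenumber/intensity", "must be numeric")
  if (length(wavenumber) != length(intensity))
    stop_field("intensity", "must match the axis length")
  if (length(wavenumber) < 2L)
    stop_field("wavenumber", "a spectrum needs at least 2 points")
  if (any(!is.finite(wavenumber)) || any(!is.finite(intensity)))
    stop_field("wavenumber/intensity", "must be finite")
  if (anyDuplicated(wavenumber))
    stop_field("wavenumber", "must not contain duplicates")
  ord <- order(wavenumber)
  structure(
    list(wavenumber = wavenumber[ord], intensity = intensity[ord],
         meta = meta),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum: %d points, %.6g-%.6g 1/cm\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

#' Read a two-column spectrum file
#'
#' Plain-text spectra: two numeric columns (wavenumber 1/cm, intensity),
#' separated by whitespace or a comma; lines starting with `#` are
#' comments. A descending axis is sorted ascending on read.
#'
#' @param path file path.
#' @param meta provenance list attached to the spectrum.
#' @return a [raman_spectrum].
#' @export
read_spectrum <- function(path, meta = list()) {
  lines <- readLines(check_file(path), warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx))
    stop(sprintf("parse error in %s: no data lines", path), call. = FALSE)
  parts <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  bad_ncol <- which(lengths(parts) != 2L)
  if (length(bad_ncol))
    stop(sprintf("parse error in %s, line %d: expected 2 columns",
                 path, idx[bad_ncol[1L]]), call. = FALSE)
  vals <- suppressWarnings(vapply(parts, as.numeric, numeric(2)))
  bad_num <- which(colSums(is.na(vals)) > 0)
  if (length(bad_num))
    stop(sprintf("parse error in %s, line %d: non-numeric value",
                 path, idx[bad_num[1L]]), call. = FALSE)
  if (ncol(vals) < 2L)
    stop(sprintf("parse error in %s: fewer than 2 data points", path),
         call. = FALSE)
  meta$source <- path
  raman_spectrum(vals[1L, ], vals[2L, ], meta = meta)
}

#' Write a spectrum to a two-column text file
#'
#' The format [read_spectrum()] reads; round-trips losslessly at the
#' stated precision.
#'
#' @param spectrum a [raman_spectrum].
#' @param path output path.
#' @param digits significant digits written (default 12).
#' @export
write_spectrum <- function(spectrum, path, digits = 12) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  lines <- sprintf("%s %s",
                   formatC(spectrum$wavenumber, digits = digits, format = "g"),
                   formatC(spectrum$intensity, digits = digits, format = "g"))
  writeLines(c("# wavenumber_cm-1 intensity", lines), path)
  invisible(path)
}

#' Bundle spectra measured on a shared axis
#'
#' A mapping measurement: many single spectra of one sample. Spectra whose
#' axes differ are resampled onto the first spectrum's grid by linear
#' interpolation (no extrapolation beyond the shared range).
#'
#' @param spectra list of [raman_spectrum] objects, non-empty.
#' @param label sample/condition label.
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, label = "") {
  if (!is.list(spectra) || !length(spectra))
    stop_field("spectra", "must be a non-empty list of spectra")
  if (!all(vapply(spectra, inherits, logical(1), "raman_spectrum")))
    stop_field("spectra", "all elements must be raman_spectrum objects")
  ref <- spectra[[1L]]$wavenumber
  same <- vapply(spectra, function(s)
    length(s$wavenumber) == length(ref) && all(s$wavenumber == ref),
    logical(1))
  if (!all(same)) {
    lo <- max(vapply(spectra, function(s) min(s$wavenumber), numeric(1)))
    hi <- min(vapply(spectra, function(s) max(s$wavenumber), numeric(1)))
    if (lo >= hi)
      stop("spectra have disjoint axis ranges", call. = FALSE)
    grid <- ref[ref >= lo & ref <= hi]
    spectra <- lapply(spectra, function(s) {
      y <- stats::approx(s$wavenumber, s$intensity, xout = grid)$y
      raman_spectrum(grid, y, meta = s$meta)
    })
  }
  structure(list(spectra = spectra, label = label), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("Spectrum set '%s': %d spectra, %d points each\n",
              x$label, length(x$spectra), length(x$spectra[[1L]]$wavenumber)))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

#' Pointwise mean spectrum of a set
#'
#' The representative averaged spectrum of a mapping measurement.
#'
#' @param set a [spectrum_set].
#' @return a [raman_spectrum] on the set's shared axis.
#' @export
mean_spectrum <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!length(set$spectra)) stop("empty spectrum set", call. = FALSE)
  mat <- vapply(set$spectra, function(s) s$intensity,
                numeric(length(set$spectra[[1L]]$wavenumber)))
  raman_spectrum(set$spectra[[1L]]$wavenumber, rowMeans(as.matrix(mat)),
                 meta = list(label = set$label, n_averaged = length(set$spectra)))
}
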