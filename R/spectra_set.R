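#' Construct a labeled set of spectra
#'
#' The dataset object every analysis stage consumes: a sites-by-
#' wavelengths reflectance matrix plus, per site, a tissue label
#' (`mucosa` or `tumor`) and a patient identifier, and the probe the
#' set was acquired with.
#'
#' @param spectra Numeric matrix, one row per measurement site, one
#'   column per wavelength. No missing values.
#' @param wavelengths Numeric vector (nm), strictly increasing, length
#'   equal to `ncol(spectra)`.
#' @param labels Character or factor, one of `"mucosa"`/`"tumor"` per
#'   site.
#' @param patient_id One identifier per site.
#' @param probe `"short_SDD"` or `"long_SDD"`.
#' @return An object of class `drs_spectra_set`.
#' @export
labeled_spectra_set <- function(spectra, wavelengths, labels, patient_id,
                                probe = c("short_SDD", "long_SDD")) {
  probe <- match.arg(probe)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(spectra) != length(wavelengths))
    stop("ncol(spectra) must equal length(wavelengths)")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (anyNA(spectra) || any(!is.finite(spectra)))
    stop("spectra must contain only finite values")
  labels <- as.character(labels)
  if (!all(labels %in% c("mucosa", "tumor")))
    stop("labels must be 'mucosa' or 'tumor'")
  if (length(labels) != nrow(spectra) || length(patient_id) != nrow(spectra))
    stop("labels and patient_id must have one entry per row of spectra")
  structure(list(spectra = spectra, wavelengths = wavelengths,
                 labels = factor(labels, levels = c("mucosa", "tumor")),
                 patient_id = as.character(patient_id), probe = probe),
            class = "drs_spectra_set")
}

#' @export
print.drs_spectra_set <- function(x, ...) {
  cat(sprintf(
    "<drs_spectra_set> %s: %d spectra (%d mucosa / %d tumor), %d patients, %d wavelengths %g-%g nm\n",
    x$probe, nrow(x$spectra), sum(x$labels == "mucosa"),
    sum(x$labels == "tumor"), length(unique(x$patient_id)),
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Write a labeled spectra set to a delimited text file
#'
#' One header row `label,patient_id,probe,<wavelength...>` followed by
#' one row per site. The round trip through [read_spectra_table()] is
#' lossless for values, labels, patient IDs and probe.
#'
#' @param set A `drs_spectra_set`.
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(set, path, sep = ",") {
  stopifnot(inherits(set, "drs_spectra_set"))
  df <- data.frame(label = as.character(set$labels),
                   patient_id = set$patient_id,
                   probe = set$probe,
                   stringsAsFactors = FALSE)
  mat <- set$spectra
  colnames(mat) <- format(set$wavelengths, trim = TRUE, scientific = FALSE)
  utils::write.table(cbind(df, mat), path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a labeled spectra set from a delimited text file
#'
#' @param path File written by [write_spectra_table()] (or any
#'   delimited file with the same layout).
#' @param sep Field separator.
#' @return A `drs_spectra_set`.
#' @export
read_spectra_table <- function(path, sep = ",") {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("spectra table needs a header and at least one row")
  split_row <- function(l) strsplit(l, sep, fixed = TRUE)[[1]]
  header <- split_row(lines[1])
  if (length(header) < 4L ||
      !identical(header[1:3], c("label", "patient_id", "probe")))
    stop("header must start with: label, patient_id, probe")
  wl <- suppressWarnings(as.numeric(header[-(1:3)]))
  if (anyNA(wl)) stop("non-numeric wavelength in header")
  n_fields <- length(header)
  rows <- lapply(lines[-1], split_row)
  len <- vapply(rows, length, integer(1))
  if (any(len != n_fields))
    stop(sprintf("row %d has %d fields, expected %d",
                 which(len != n_fields)[1] + 1L,
                 len[len != n_fields][1], n_fields))
  labels <- vapply(rows, `[`, character(1), 1L)
  bad_lab <- which(!labels %in% c("mucosa", "tumor"))
  if (length(bad_lab))
    stop(sprintf("unknown label '%s' in row %d", labels[bad_lab[1]],
                 bad_lab[1] + 1L))
  patient_id <- vapply(rows, `[`, character(1), 2L)
  probe <- unique(vapply(rows, `[`, character(1), 3L))
  if (length(probe) != 1L) stop("mixed probe identifiers in one table")
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(wl))
  for (r in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[r]][-(1:3)]))
    if (anyNA(v)) stop(sprintf("non-numeric value in row %d", r + 1L))
    vals[r, ] <- v
  }
  labeled_spectra_set(vals, wl, labels, patient_id, probe)
}

#' Restrict a spectra set to a set of wavelength bands
#'
#' Keeps only the wavelength columns that fall inside at least one of
#' the given bands (interval endpoints inclusive). Accepts a
#' [select_bands()] result or any data frame / matrix with `lo` and
#' `hi` columns, so user-specified band lists and unions of bands can
#' be run through the identical classification protocol.
#'
#' @param set A `drs_spectra_set`.
#' @param bands A `drs_band_set`, or a 2-column structure of interval
#'   bounds in nm.
#' @return A `drs_spectra_set` with the restricted wavelength grid.
#' @export
restrict_dataset <- function(set, bands) {
  stopifnot(inherits(set, "drs_spectra_set"))
  b <- as_band_matrix(bands)
  keep <- rep(FALSE, length(set$wavelengths))
  for (r in seq_len(nrow(b)))
    keep <- keep | (set$wavelengths >= b[r, 1] & set$wavelengths <= b[r, 2])
  if (!any(keep))
    stop("no wavelengths of the set fall inside the requested bands")
  labeled_spectra_set(set$spectra[, keep, drop = FALSE],
                      set$wavelengths[keep],
                      as.character(set$labels), set$patient_id, set$probe)
}

# normalize band representations to a matrix with columns lo, hi
as_band_matrix <- function(bands) {
  if (inherits(bands, "drs_band_set")) bands <- bands$bands
  if (is.data.frame(bands)) bands <- as.matrix(bands[, c("lo", "hi")])
  if (is.null(dim(bands))) bands <- matrix(bands, ncol = 2, byrow = TRUE)
  bands <- as.matrix(bands)
  if (ncol(bands) != 2L || any(bands[, 1] >= bands[, 2]))
    stop("bands must be intervals with lo < hi")
  bands[order(bands[, 1]), , drop = FALSE]
}
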