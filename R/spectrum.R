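#' Construct a spectrum
#'
#' A spectrum is the basic measurement unit of the package: a strictly
#' increasing wavelength grid in nanometres together with one value per
#' wavelength, either raw detector counts (`kind = "intensity"`) or
#' dimensionless diffuse reflectance (`kind = "reflectance"`).
#'
#' @param wavelengths Numeric vector of wavelengths (nm), strictly
#'   increasing, finite, length >= 2.
#' @param values Numeric vector of the same length; finite.
#' @param kind Either `"reflectance"` or `"intensity"`.
#' @return An object of class `drs_spectrum` (a list with elements
#'   `wavelengths`, `values`, `kind`).
#' @examples
#' s <- spectrum(400:700, rep(0.5, 301))
#' range(s$wavelengths)
#' @export
spectrum <- function(wavelengths, values, kind = c("reflectance", "intensity")) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) < 2L)
    stop("a spectrum needs at least 2 wavelengths")
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelengths must be finite")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (length(values) != length(wavelengths))
    stop("values and wavelengths must have equal length")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite")
  structure(list(wavelengths = wavelengths, values = values, kind = kind),
            class = "drs_spectrum")
}

#' @export
print.drs_spectrum <- function(x, ...) {
  cat(sprintf("<drs_spectrum> %s, %d points, %g-%g nm\n",
              x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Bundle the raw intensity triple of one measurement site
#'
#' Holds the three detector readings needed to turn counts into
#' reflectance: the tissue reading, the background (probe in the closed
#' holder, light path blocked) and the reading off the diffuse
#' reflectance standard, all on one shared wavelength grid.
#'
#' @param tissue,background,reference `drs_spectrum` objects of kind
#'   `"intensity"` sharing one wavelength grid.
#' @param reference_reflectivity Reflectivity of the reference standard:
#'   a scalar in (0, 1] or a `drs_spectrum` on the same grid.
#' @return An object of class `drs_raw_measurement`.
#' @export
raw_measurement <- function(tissue, background, reference,
                            reference_reflectivity = 0.99) {
  for (s in list(tissue, background, reference))
    if (!inherits(s, "drs_spectrum")) stop("inputs must be drs_spectrum objects")
  if (!isTRUE(all.equal(tissue$wavelengths, background$wavelengths)) ||
      !isTRUE(all.equal(tissue$wavelengths, reference$wavelengths)))
    stop("tissue, background and reference must share one wavelength grid")
  if (inherits(reference_reflectivity, "drs_spectrum")) {
    if (!isTRUE(all.equal(reference_reflectivity$wavelengths, tissue$wavelengths)))
      stop("reference_reflectivity spectrum must share the measurement grid")
    rr <- reference_reflectivity$values
  } else {
    rr <- as.numeric(reference_reflectivity)
    if (length(rr) != 1L) stop("reference_reflectivity must be scalar or a spectrum")
  }
  if (any(rr <= 0) || any(rr > 1))
    stop("reference_reflectivity must lie in (0, 1]")
  structure(list(tissue = tissue, background = background,
                 reference = reference, reference_reflectivity = rr),
            class = "drs_raw_measurement")
}

#' Instrument profile of the dual-spectrometer system
#'
#' Describes the two-spectrometer layout: a visible/NIR spectrometer, a
#' NIR/SWIR spectrometer, the overlap region where their readings are
#' blended, and the common output grid all merged spectra are reported
#' on.
#'
#' @param vis_range,nir_range Wavelength coverage (nm) of the two
#'   spectrometers.
#' @param overlap Overlap interval used for blending; must lie inside
#'   both ranges.
#' @param grid_step Step of the uniform output grid in nm.
#' @return An object of class `drs_instrument_profile` with an
#'   `output_grid` covering the union of both ranges.
#' @export
instrument_profile <- function(vis_range = c(350, 1140),
                               nir_range = c(1090, 1920),
                               overlap = c(1090, 1140),
                               grid_step = 1) {
  stopifnot(length(vis_range) == 2L, length(nir_range) == 2L,
            length(overlap) == 2L, overlap[1] < overlap[2], grid_step > 0)
  if (overlap[1] < max(vis_range[1], nir_range[1]) ||
      overlap[2] > min(vis_range[2], nir_range[2]))
    stop("overlap must lie inside the intersection of vis_range and nir_range")
  grid <- seq(min(vis_range[1], nir_range[1]),
              max(vis_range[2], nir_range[2]), by = grid_step)
  structure(list(vis_range = vis_range, nir_range = nir_range,
                 overlap = overlap, output_grid = grid),
            class = "drs_instrument_profile")
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; values at grid points shared with the input are
#' reproduced exactly. Extrapolation outside the input span is refused.
#'
#' @param s A `drs_spectrum`.
#' @param grid Target wavelengths (nm) within the span of `s`.
#' @return A `drs_spectrum` on `grid` with the same `kind`.
#' @export
resample <- function(s, grid) {
  stopifnot(inherits(s, "drs_spectrum"))
  grid <- as.numeric(grid)
  if (min(grid) < min(s$wavelengths) || max(grid) > max(s$wavelengths))
    stop(sprintf("resample would extrapolate: grid [%g, %g] vs spectrum [%g, %g]",
                 min(grid), max(grid), min(s$wavelengths), max(s$wavelengths)))
  v <- stats::approx(s$wavelengths, s$values, xout = grid)$y
  spectrum(grid, v, kind = s$kind)
}
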