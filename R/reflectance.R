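#' Compute diffuse reflectance from a raw intensity triple
#'
#' Converts detector counts to dimensionless reflectance by background
#' subtraction and normalisation against the reflectance standard:
#'
#' \deqn{R(\lambda) = \frac{1}{\rho_{ref}} \cdot
#'   \frac{I_{tissue}(\lambda) - I_{bg}(\lambda)}
#'        {I_{ref}(\lambda) - I_{bg}(\lambda)}}
#'
#' where \eqn{\rho_{ref}} is the known reflectivity of the standard.
#'
#' @param raw A [raw_measurement()] object.
#' @param clip_negative If `TRUE` (default), reflectance values driven
#'   below zero by detector noise are clipped to 0 with a warning;
#'   physical reflectance is non-negative.
#' @return A `drs_spectrum` of kind `"reflectance"`.
#' @export
compute_reflectance <- function(raw, clip_negative = TRUE) {
  stopifnot(inherits(raw, "drs_raw_measurement"))
  wl <- raw$tissue$wavelengths
  denom <- raw$reference$values - raw$background$values
  bad <- which(denom <= 0)
  if (length(bad))
    stop(sprintf(
      "reference minus background is non-positive at %d wavelength(s): %s",
      length(bad),
      paste(utils::head(wl[bad], 5), collapse = ", ")))
  r <- (raw$tissue$values - raw$background$values) / denom /
    raw$reference_reflectivity
  if (any(r < 0)) {
    if (clip_negative) {
      warning(sprintf("%d negative reflectance value(s) clipped to 0",
                      sum(r < 0)))
      r <- pmax(r, 0)
    }
  }
  spectrum(wl, r, kind = "reflectance")
}

#' Merge visible and NIR spectrometer reflectance into one broadband spectrum
#'
#' Below the overlap region the output follows the visible spectrometer,
#' above it the NIR spectrometer. Inside the overlap both spectra are
#' interpolated onto 101 evenly spaced points indexed \eqn{i = 0..100}
#' and blended with the weighted sum
#' \deqn{R_i = \frac{(100 - i)\, R_{VIS,i} + i\, R_{NIR,i}}{100},}
#' so the contribution ramps linearly from pure VIS at the lower overlap
#' edge to pure NIR at the upper edge and the result is continuous at
#' both edges. The merged curve is finally interpolated onto the
#' profile's common output grid.
#'
#' @param vis,nir Reflectance `drs_spectrum` objects covering the
#'   profile's `vis_range` and `nir_range` respectively.
#' @param profile An [instrument_profile()].
#' @return A `drs_spectrum` of kind `"reflectance"` on
#'   `profile$output_grid`.
#' @export
merge_spectra <- function(vis, nir, profile = instrument_profile()) {
  stopifnot(inherits(vis, "drs_spectrum"), inherits(nir, "drs_spectrum"),
            inherits(profile, "drs_instrument_profile"))
  ov <- profile$overlap
  if (min(vis$wavelengths) > ov[1] || max(vis$wavelengths) < ov[2])
    stop("vis spectrum does not cover the overlap region")
  if (min(nir$wavelengths) > ov[1] || max(nir$wavelengths) < ov[2])
    stop("nir spectrum does not cover the overlap region")

  grid <- profile$output_grid
  grid <- grid[grid >= min(vis$wavelengths) & grid <= max(nir$wavelengths)]

  # 101-point blending grid across the overlap, i = 0..100
  i <- 0:100
  wl_ov <- ov[1] + i / 100 * (ov[2] - ov[1])
  v_ov <- stats::approx(vis$wavelengths, vis$values, xout = wl_ov)$y
  n_ov <- stats::approx(nir$wavelengths, nir$values, xout = wl_ov)$y
  blended <- ((100 - i) * v_ov + i * n_ov) / 100

  lo <- grid < ov[1]
  hi <- grid > ov[2]
  mid <- !lo & !hi
  out <- numeric(length(grid))
  if (any(lo))
    out[lo] <- stats::approx(vis$wavelengths, vis$values, xout = grid[lo])$y
  if (any(hi))
    out[hi] <- stats::approx(nir$wavelengths, nir$values, xout = grid[hi])$y
  if (any(mid))
    out[mid] <- stats::approx(wl_ov, blended, xout = grid[mid])$y
  spectrum(grid, out, kind = "reflectance")
}
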