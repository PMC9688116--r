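#' Chromophore absorption library
#'
#' Specific absorption curves for the four chromophores the pipeline
#' attributes spectral features to: deoxyhemoglobin (Hb), oxyhemoglobin
#' (HbO2), water and lipid, defined over 350-1920 nm.
#'
#' The curves are parametric approximations — sums of Gaussian bands on
#' smooth baselines — with band centres fixed at the chromophores'
#' established absorption peaks: HbO2 at 414, 542 and 576 nm; Hb at
#' 433, 556 and 757 nm; the lipid double peak between 1700 and 1800 nm
#' (plus its 761, 930 and 1210 nm bands); water bands near 970, 1200,
#' 1440 nm and the steep rise toward 1900 nm. Magnitudes are on
#' literature scale (per mm): hemoglobin curves are expressed per
#' "blood unit" (an arbitrary-but-consistent concentration unit, since
#' only class contrast matters downstream), water and lipid per unit
#' volume fraction.
#'
#' @return An object of class `drs_chromophore_library`: a named list
#'   of functions mapping a wavelength grid (nm) to absorption (mm^-1).
#' @seealso [absorption()], [mu_a()]
#' @export
chromophore_library <- function() {
  g <- function(center, width, amp)
    function(wl) amp * exp(-(wl - center)^2 / (2 * width^2))
  sum_bands <- function(...) {
    fs <- list(...)
    function(wl) Reduce(`+`, lapply(fs, function(f) f(wl)))
  }
  lib <- list(
    HbO2 = sum_bands(
      g(414, 12, 1.50), g(542, 13, 0.30), g(576, 11, 0.32),
      function(wl) 0.0015 + 0.08 * exp(-(wl - 350) / 60)),
    Hb = sum_bands(
      g(433, 14, 1.20), g(556, 18, 0.28), g(757, 22, 0.035),
      function(wl) 0.0015 + 0.10 * exp(-(wl - 350) / 60)),
    water = sum_bands(
      g(970, 35, 0.0045), g(1200, 45, 0.010), g(1440, 60, 0.30),
      g(1930, 80, 1.20),
      function(wl) 1e-4 + 0 * wl),
    lipid = sum_bands(
      g(761, 18, 0.0012), g(930, 25, 0.012), g(1210, 35, 0.060),
      g(1724, 16, 0.45), g(1760, 14, 0.38),
      function(wl) 1e-4 + 0 * wl)
  )
  structure(lib, class = "drs_chromophore_library",
            domain = c(350, 1920))
}

#' Sample a chromophore absorption curve on a wavelength grid
#'
#' @param chromophore One of `"Hb"`, `"HbO2"`, `"water"`, `"lipid"`.
#' @param grid Wavelengths (nm) within 350-1920.
#' @param lib A [chromophore_library()].
#' @return A `drs_spectrum` (absorption in mm^-1; stored with kind
#'   `"intensity"` since it is not a reflectance).
#' @export
absorption <- function(chromophore, grid, lib = chromophore_library()) {
  stopifnot(inherits(lib, "drs_chromophore_library"))
  if (!chromophore %in% names(lib))
    stop(sprintf("unknown chromophore '%s' (library has: %s)",
                 chromophore, paste(names(lib), collapse = ", ")))
  dom <- attr(lib, "domain")
  if (min(grid) < dom[1] || max(grid) > dom[2])
    stop(sprintf("grid must lie within %g-%g nm", dom[1], dom[2]))
  spectrum(grid, lib[[chromophore]](as.numeric(grid)), kind = "intensity")
}

#' Export the chromophore library as a table
#'
#' @param grid Wavelength grid (nm).
#' @param lib A [chromophore_library()].
#' @return A data frame with columns `wavelength`, `Hb`, `HbO2`,
#'   `water`, `lipid` (absorption in mm^-1).
#' @export
chromophore_table <- function(grid = seq(350, 1920, by = 5),
                              lib = chromophore_library()) {
  data.frame(
    wavelength = grid,
    Hb = absorption("Hb", grid, lib)$values,
    HbO2 = absorption("HbO2", grid, lib)$values,
    water = absorption("water", grid, lib)$values,
    lipid = absorption("lipid", grid, lib)$values)
}

#' Describe a tissue by its optical composition
#'
#' @param total_hemoglobin Total hemoglobin concentration in "blood
#'   units" (arbitrary-but-consistent; the library's hemoglobin curves
#'   are per unit).
#' @param StO2 Blood oxygen saturation, fraction in \[0, 1\].
#' @param water_fraction,lipid_fraction Volume fractions in \[0, 1\].
#' @param scatter_amplitude Reduced scattering coefficient (mm^-1) at
#'   the reference wavelength; > 0.
#' @param scatter_power Scattering power-law exponent; >= 0.
#' @param lambda0 Reference wavelength for scattering (nm).
#' @return An object of class `drs_tissue_composition`.
#' @export
tissue_composition <- function(total_hemoglobin = 1.0, StO2 = 0.75,
                               water_fraction = 0.65, lipid_fraction = 0.10,
                               scatter_amplitude = 2.0, scatter_power = 1.2,
                               lambda0 = 500) {
  stopifnot(total_hemoglobin >= 0,
            StO2 >= 0, StO2 <= 1,
            water_fraction >= 0, water_fraction <= 1,
            lipid_fraction >= 0, lipid_fraction <= 1,
            scatter_amplitude > 0, scatter_power >= 0, lambda0 > 0)
  structure(list(total_hemoglobin = total_hemoglobin, StO2 = StO2,
                 water_fraction = water_fraction,
                 lipid_fraction = lipid_fraction,
                 scatter_amplitude = scatter_amplitude,
                 scatter_power = scatter_power, lambda0 = lambda0),
            class = "drs_tissue_composition")
}

#' Absorption coefficient of a tissue composition
#'
#' Linear mixing of the library curves:
#' \deqn{\mu_a(\lambda) = tHb\,[StO_2\,\epsilon_{HbO_2}(\lambda) +
#'   (1 - StO_2)\,\epsilon_{Hb}(\lambda)] +
#'   f_{water}\,\mu_{a,water}(\lambda) +
#'   f_{lipid}\,\mu_{a,lipid}(\lambda)}
#'
#' @param comp A [tissue_composition()].
#' @param grid Wavelength grid (nm).
#' @param lib A [chromophore_library()].
#' @return A `drs_spectrum` of absorption in mm^-1.
#' @export
mu_a <- function(comp, grid, lib = chromophore_library()) {
  stopifnot(inherits(comp, "drs_tissue_composition"))
  grid <- as.numeric(grid)
  v <- comp$total_hemoglobin *
    (comp$StO2 * lib$HbO2(grid) + (1 - comp$StO2) * lib$Hb(grid)) +
    comp$water_fraction * lib$water(grid) +
    comp$lipid_fraction * lib$lipid(grid)
  spectrum(grid, v, kind = "intensity")
}

#' Reduced scattering coefficient of a tissue composition
#'
#' Power law \eqn{\mu_s'(\lambda) = a (\lambda/\lambda_0)^{-b}},
#' strictly decreasing in wavelength for `b > 0`.
#'
#' @inheritParams mu_a
#' @return A `drs_spectrum` of reduced scattering in mm^-1.
#' @export
mu_s_prime <- function(comp, grid) {
  stopifnot(inherits(comp, "drs_tissue_composition"))
  grid <- as.numeric(grid)
  v <- comp$scatter_amplitude * (grid / comp$lambda0)^(-comp$scatter_power)
  spectrum(grid, v, kind = "intensity")
}

#' Wavelength bands used for chromophore and scattering attribution
#'
#' Named intervals in which each chromophore shows its characteristic
#' absorption features, used by [attribute_chromophores()] for shape
#' matching, plus the low-absorption windows in which a flat monotone
#' loading is read as a scattering signature.
#'
#' @param hemoglobin,water,lipid Lists of `c(lo, hi)` intervals (nm).
#'   The hemoglobin bands apply to both Hb and HbO2.
#' @param vis_scatter,nir_scatter Flatness windows for scattering
#'   attribution (nm); together they span the 600-1350 nm
#'   low-absorption window.
#' @return An object of class `drs_attribution_bands`.
#' @export
attribution_bands <- function(
    hemoglobin = list(c(380, 450), c(530, 590), c(740, 780)),
    water = list(c(950, 1000), c(1150, 1250), c(1380, 1500), c(1850, 1920)),
    lipid = list(c(740, 780), c(1150, 1250), c(1700, 1800)),
    vis_scatter = c(600, 1000),
    nir_scatter = c(1000, 1350)) {
  chk <- function(b) {
    stopifnot(length(b) == 2L, b[1] < b[2], b[1] >= 350, b[2] <= 1920)
    b
  }
  structure(list(
    chromophores = list(
      Hb = lapply(hemoglobin, chk),
      HbO2 = lapply(hemoglobin, chk),
      water = lapply(water, chk),
      lipid = lapply(lipid, chk)),
    scattering = list(vis = chk(vis_scatter), nir = chk(nir_scatter))),
    class = "drs_attribution_bands")
}
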