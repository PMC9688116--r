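#' Probe geometry
#'
#' @param name `"short_SDD"` (630 µm source-detector distance, probing
#'   roughly 0.5-1 mm deep) or `"long_SDD"` (2500 µm, probing roughly
#'   0.5-1.9 mm deep).
#' @param sdd Source-detector distance in µm; defaults to the named
#'   probe's distance.
#' @return An object of class `drs_probe_geometry`.
#' @export
probe_geometry <- function(name = c("short_SDD", "long_SDD"), sdd = NULL) {
  name <- match.arg(name)
  if (is.null(sdd)) sdd <- if (name == "short_SDD") 630 else 2500
  stopifnot(sdd > 0)
  structure(list(name = name, sdd = sdd), class = "drs_probe_geometry")
}

#' Forward model configuration
#'
#' @param model `"diffusion"` for the steady-state diffusion
#'   approximation (Farrell-type) local reflectance of a semi-infinite
#'   homogeneous medium, or `"exp_attenuation"` for a simple
#'   exponential-attenuation fallback usable in degenerate regimes.
#' @param n Tissue refractive index (mismatch against air), used for
#'   the extrapolated boundary of the diffusion model.
#' @param grid Output wavelength grid (nm).
#' @return An object of class `drs_forward_config`.
#' @export
forward_model_config <- function(model = c("diffusion", "exp_attenuation"),
                                 n = 1.4,
                                 grid = seq(350, 1920, by = 1)) {
  model <- match.arg(model)
  stopifnot(n >= 1, length(grid) >= 2)
  structure(list(model = model, n = n, grid = as.numeric(grid)),
            class = "drs_forward_config")
}

# Farrell-type steady-state diffusion reflectance of a semi-infinite
# homogeneous medium at source-detector separation rho (mm).
# mua, musp in mm^-1 (vectors or matrices); returns same shape, mm^-2
# scaled to a dimensionless local reflectance (see forward_reflectance).
farrell_reflectance <- function(mua, musp, rho, n = 1.4) {
  mut <- mua + musp
  albedo <- musp / mut
  mueff <- sqrt(3 * mua * mut)
  z0 <- 1 / mut
  # internal reflection parameter for the refractive-index mismatch
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  A <- (1 + rd) / (1 - rd)
  zb <- 2 * A / (3 * mut)
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  albedo / (4 * pi) * (
    z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
      (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2)
}

# internal: reflectance values for one composition on cfg$grid
forward_values <- function(comp, probe, cfg, lib = chromophore_library()) {
  mua <- mu_a(comp, cfg$grid, lib)$values
  musp <- mu_s_prime(comp, cfg$grid)$values
  forward_values_raw(mua, musp, probe, cfg)
}

forward_values_raw <- function(mua, musp, probe, cfg) {
  if (any(musp <= 0))
    stop("diffusion model requires mu_s' > 0 at every wavelength")
  rho <- probe$sdd / 1000 # mm
  if (cfg$model == "diffusion") {
    r <- farrell_reflectance(mua, musp, rho, cfg$n)
  } else {
    # exponential attenuation over an effective path ~ rho
    r <- exp(-sqrt(3 * mua * (mua + musp)) * rho)
  }
  pmin(r, 1)
}

#' Simulate the diffuse reflectance spectrum of a homogeneous tissue
#'
#' Evaluates the configured forward model (default: the steady-state
#' diffusion approximation of a semi-infinite homogeneous medium,
#' evaluated at the probe's source-detector separation) on the tissue's
#' absorption and reduced scattering spectra. The returned local
#' reflectance is dimensionless, lies in (0, 1], decreases when
#' absorption increases, and decreases with source-detector distance.
#'
#' @param comp A [tissue_composition()].
#' @param probe A [probe_geometry()].
#' @param cfg A [forward_model_config()].
#' @param lib A [chromophore_library()].
#' @return A `drs_spectrum` of kind `"reflectance"` on `cfg$grid`.
#' @export
forward_reflectance <- function(comp, probe = probe_geometry("short_SDD"),
                                cfg = forward_model_config(),
                                lib = chromophore_library()) {
  stopifnot(inherits(comp, "drs_tissue_composition"),
            inherits(probe, "drs_probe_geometry"),
            inherits(cfg, "drs_forward_config"))
  spectrum(cfg$grid, forward_values(comp, probe, cfg, lib),
           kind = "reflectance")
}
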