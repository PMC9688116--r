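#' Specify a synthetic two-class study population
#'
#' Describes the statistical structure of a simulated clinical DRS
#' study: the mean optical composition of each tissue class, log-normal
#' patient-level and site-level variability applied on top of the class
#' means, the cohort layout (patients, measurement sites per patient
#' and class) and the detector noise model.
#'
#' The default class contrast makes tumor tissue relative to mucosa:
#' total hemoglobin x2.0, StO2 0.75 -> 0.60, water fraction
#' 0.65 -> 0.70, lipid fraction 0.10 -> 0.05 and scattering amplitude
#' x1.2 — directionally the blood/water/lipid/scattering differences
#' that drive mucosa-tumor discrimination. `contrast = "null"` gives
#' identical class means (for calibration experiments).
#'
#' @param contrast `"default"` for the contrast above, `"null"` for
#'   identical class means; ignored when `mucosa`/`tumor` are given.
#' @param mucosa,tumor Optional explicit [tissue_composition()] class
#'   means.
#' @param patient_cv,site_cv Log-normal coefficients of variation of
#'   the patient-level and site-level multiplicative effects (defaults
#'   0.2 and 0.1). The patient effect is drawn once per patient and
#'   shared by both tissue classes of that patient, mirroring paired
#'   sampling of mucosa and tumor from the same resection specimen.
#' @param n_patients Number of patients (default 47).
#' @param sites_per_patient Measurement sites per patient per class
#'   (default 15).
#' @param noise_rel,noise_add Relative (multiplicative) and additive
#'   Gaussian noise standard deviations applied per spectrometer draw;
#'   both are tripled above 1850 nm where detector sensitivity falls.
#' @param seed Integer seed making the generated dataset reproducible.
#' @return An object of class `drs_population_spec`.
#' @export
population_spec <- function(contrast = c("default", "null"),
                            mucosa = NULL, tumor = NULL,
                            patient_cv = 0.2, site_cv = 0.1,
                            n_patients = 47, sites_per_patient = 15,
                            noise_rel = 0.01, noise_add = 1e-4,
                            seed = 1L) {
  contrast <- match.arg(contrast)
  if (is.null(mucosa)) mucosa <- tissue_composition()
  if (is.null(tumor)) {
    tumor <- if (contrast == "null") mucosa else
      tissue_composition(
        total_hemoglobin = mucosa$total_hemoglobin * 2.0,
        StO2 = 0.60,
        water_fraction = 0.70,
        lipid_fraction = 0.05,
        scatter_amplitude = mucosa$scatter_amplitude * 1.2,
        scatter_power = mucosa$scatter_power,
        lambda0 = mucosa$lambda0)
  }
  stopifnot(inherits(mucosa, "drs_tissue_composition"),
            inherits(tumor, "drs_tissue_composition"),
            patient_cv >= 0, site_cv >= 0,
            n_patients >= 1, sites_per_patient >= 1,
            noise_rel >= 0, noise_add >= 0)
  structure(list(mucosa = mucosa, tumor = tumor,
                 patient_cv = patient_cv, site_cv = site_cv,
                 n_patients = as.integer(n_patients),
                 sites_per_patient = as.integer(sites_per_patient),
                 noise_rel = noise_rel, noise_add = noise_add,
                 seed = as.integer(seed)),
            class = "drs_population_spec")
}

# parameters that receive hierarchical multiplicative variability
.var_params <- c("total_hemoglobin", "StO2", "water_fraction",
                 "lipid_fraction", "scatter_amplitude")

# sd of log for a log-normal with coefficient of variation cv
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Draw one tissue composition from the hierarchical population model
#'
#' The sampled composition is the class mean with each concentration-
#' like parameter multiplied by `exp(patient effect)` and
#' `exp(site effect)`; fractions (StO2, water, lipid) are then
#' truncated to \[0, 1\]. With both CVs zero every sample equals the
#' class mean.
#'
#' @param class `"mucosa"` or `"tumor"`.
#' @param spec A [population_spec()].
#' @param patient_z,site_z Optional standard-normal vectors (one per
#'   varying parameter) representing the patient and site effects; when
#'   `NULL` they are drawn from the current RNG stream. Passing the
#'   patient's `patient_z` to all of that patient's sites shares the
#'   patient effect across both classes.
#' @return A [tissue_composition()].
#' @export
sample_tissue <- function(class = c("mucosa", "tumor"), spec,
                          patient_z = NULL, site_z = NULL) {
  class <- match.arg(class)
  stopifnot(inherits(spec, "drs_population_spec"))
  base <- spec[[class]]
  k <- length(.var_params)
  if (is.null(patient_z)) patient_z <- stats::rnorm(k)
  if (is.null(site_z)) site_z <- stats::rnorm(k)
  mult <- exp(patient_z * cv_to_sdlog(spec$patient_cv) +
                site_z * cv_to_sdlog(spec$site_cv))
  p <- unlist(base[.var_params]) * mult
  names(p) <- .var_params
  tissue_composition(
    total_hemoglobin = p["total_hemoglobin"],
    StO2 = min(1, p["StO2"]),
    water_fraction = min(1, p["water_fraction"]),
    lipid_fraction = min(1, p["lipid_fraction"]),
    scatter_amplitude = p["scatter_amplitude"],
    scatter_power = base$scatter_power,
    lambda0 = base$lambda0)
}

# draw composition parameter rows for a whole cohort; returns a matrix
# (n_patients * sites * 2 classes) x 7 plus label/patient bookkeeping
sample_cohort_params <- function(spec) {
  k <- length(.var_params)
  sdp <- cv_to_sdlog(spec$patient_cv)
  sds <- cv_to_sdlog(spec$site_cv)
  n_rows <- spec$n_patients * spec$sites_per_patient * 2L
  P <- matrix(NA_real_, n_rows, k, dimnames = list(NULL, .var_params))
  labels <- character(n_rows)
  patient <- character(n_rows)
  b_pow <- numeric(n_rows)
  l0 <- numeric(n_rows)
  row <- 0L
  for (p in seq_len(spec$n_patients)) {
    zp <- stats::rnorm(k) * sdp # one patient effect, shared by both classes
    for (cl in c("mucosa", "tumor")) {
      base <- unlist(spec[[cl]][.var_params])
      for (s in seq_len(spec$sites_per_patient)) {
        zs <- stats::rnorm(k) * sds
        row <- row + 1L
        P[row, ] <- base * exp(zp + zs)
        labels[row] <- cl
        patient[row] <- sprintf("P%02d", p)
        b_pow[row] <- spec[[cl]]$scatter_power
        l0[row] <- spec[[cl]]$lambda0
      }
    }
  }
  P[, "StO2"] <- pmin(1, P[, "StO2"])
  P[, "water_fraction"] <- pmin(1, P[, "water_fraction"])
  P[, "lipid_fraction"] <- pmin(1, P[, "lipid_fraction"])
  list(params = P, labels = labels, patient = patient,
       scatter_power = b_pow, lambda0 = l0)
}

# vectorized optical properties for a cohort parameter matrix
cohort_optics <- function(cohort, grid, lib) {
  P <- cohort$params
  E_hbo2 <- lib$HbO2(grid); E_hb <- lib$Hb(grid)
  E_w <- lib$water(grid); E_l <- lib$lipid(grid)
  mua <- outer(P[, "total_hemoglobin"] * P[, "StO2"], E_hbo2) +
    outer(P[, "total_hemoglobin"] * (1 - P[, "StO2"]), E_hb) +
    outer(P[, "water_fraction"], E_w) +
    outer(P[, "lipid_fraction"], E_l)
  musp <- P[, "scatter_amplitude"] *
    exp(-outer(cohort$scatter_power, log(grid / cohort$lambda0[1])))
  list(mua = mua, musp = musp)
}

# triplicate-averaged detector noise applied to a clean matrix
apply_noise <- function(clean, grid, spec) {
  mult <- ifelse(grid > 1850, 3, 1)
  rel <- spec$noise_rel * mult
  add <- spec$noise_add * mult
  acc <- 0
  for (rep in 1:3) {
    eps_rel <- matrix(stats::rnorm(length(clean)), nrow(clean))
    eps_add <- matrix(stats::rnorm(length(clean)), nrow(clean))
    draw <- clean * (1 + sweep(eps_rel, 2, rel, `*`)) +
      sweep(eps_add, 2, add, `*`)
    acc <- acc + draw
  }
  pmax(acc / 3, 0)
}

#' Simulate a labeled DRS dataset
#'
#' Generates a full synthetic cohort: for every patient a shared
#' patient effect, for every site a site effect, tissue compositions
#' for both classes, clean reflectance from the forward model, and
#' detector noise averaged over a triplicate measurement per site (the
#' acquisition convention of clinical DRS protocols).
#'
#' @param spec A [population_spec()]; its `seed` makes the dataset
#'   bit-reproducible.
#' @param probe A [probe_geometry()].
#' @param cfg A [forward_model_config()].
#' @param lib A [chromophore_library()].
#' @param return_raw If `TRUE`, the two spectrometer halves (visible
#'   and NIR) receive independent noise and are merged through
#'   [merge_spectra()], exercising the dual-spectrometer path; the
#'   result then also carries the raw halves. If `FALSE` (default)
#'   noise is applied once on the full grid.
#' @param profile Instrument profile used when `return_raw = TRUE`.
#' @return A `drs_spectra_set` with
#'   `n_patients * sites_per_patient * 2` rows. When
#'   `return_raw = TRUE`, a list with elements `set`, `vis`, `nir`.
#' @export
simulate_dataset <- function(spec, probe = probe_geometry("short_SDD"),
                             cfg = forward_model_config(),
                             lib = chromophore_library(),
                             return_raw = FALSE,
                             profile = NULL) {
  stopifnot(inherits(spec, "drs_population_spec"),
            inherits(probe, "drs_probe_geometry"),
            inherits(cfg, "drs_forward_config"))
  set.seed(spec$seed)
  cohort <- sample_cohort_params(spec)
  grid <- cfg$grid
  opt <- cohort_optics(cohort, grid, lib)
  clean <- forward_values_raw(opt$mua, opt$musp, probe, cfg)

  if (!return_raw) {
    noisy <- apply_noise(clean, grid, spec)
    return(labeled_spectra_set(noisy, grid, cohort$labels, cohort$patient,
                               probe$name))
  }

  if (is.null(profile)) {
    step <- grid[2] - grid[1]
    profile <- instrument_profile(
      vis_range = c(min(grid), 1140), nir_range = c(1090, max(grid)),
      grid_step = step)
  }
  vis_idx <- grid >= profile$vis_range[1] & grid <= profile$vis_range[2]
  nir_idx <- grid >= profile$nir_range[1] & grid <= profile$nir_range[2]
  vis_noisy <- apply_noise(clean[, vis_idx, drop = FALSE], grid[vis_idx], spec)
  nir_noisy <- apply_noise(clean[, nir_idx, drop = FALSE], grid[nir_idx], spec)
  merged <- matrix(NA_real_, nrow(clean), length(grid))
  for (r in seq_len(nrow(clean))) {
    m <- merge_spectra(spectrum(grid[vis_idx], vis_noisy[r, ]),
                       spectrum(grid[nir_idx], nir_noisy[r, ]),
                       profile)
    merged[r, ] <- stats::approx(m$wavelengths, m$values, xout = grid)$y
  }
  list(set = labeled_spectra_set(merged, grid, cohort$labels,
                                 cohort$patient, probe$name),
       vis = list(wavelengths = grid[vis_idx], spectra = vis_noisy),
       nir = list(wavelengths = grid[nir_idx], spectra = nir_noisy))
}
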