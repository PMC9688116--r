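#' Default pipeline run configuration
#'
#' A run configuration is a plain, fully serializable list; a stored
#' configuration plus its seed reproduces a run bit-identically. One
#' global `seed` fans out to per-stage seeds by fixed offsets:
#' simulation uses `seed + probe index`, classification uses
#' `seed + 100 + band-set index`.
#'
#' @param seed Global integer seed.
#' @param probes Character vector of probes to run.
#' @param grid_step Wavelength grid step in nm (grid spans
#'   350-1920 nm).
#' @param contrast `"default"` or `"null"` population contrast.
#' @param n_patients,sites_per_patient Cohort layout.
#' @param alpha Band-selection significance threshold.
#' @param min_run,max_gap Band-extraction run parameters (grid
#'   points).
#' @param k_components,k_nn,iterations Classifier protocol.
#' @param leakage_free Refit scaling/PLS inside folds.
#' @param band_sets Optional named list of extra band lists (each a
#'   list of `c(lo, hi)` intervals) evaluated alongside the
#'   statistically selected bands.
#' @param r_threshold,flatness_threshold,monotone_threshold
#'   Attribution thresholds.
#' @return A named list of class `drs_run_config`.
#' @export
default_run_config <- function(seed = 1L,
                               probes = c("short_SDD", "long_SDD"),
                               grid_step = 2,
                               contrast = "default",
                               n_patients = 47, sites_per_patient = 15,
                               alpha = 0.001, min_run = 3, max_gap = 0,
                               k_components = 4, k_nn = 10, iterations = 20,
                               leakage_free = FALSE,
                               band_sets = NULL,
                               r_threshold = 0.6, flatness_threshold = 2,
                               monotone_threshold = 0.8) {
  structure(list(seed = as.integer(seed), probes = probes,
                 grid_step = grid_step, contrast = contrast,
                 n_patients = n_patients,
                 sites_per_patient = sites_per_patient,
                 alpha = alpha, min_run = min_run, max_gap = max_gap,
                 k_components = k_components, k_nn = k_nn,
                 iterations = iterations, leakage_free = leakage_free,
                 band_sets = band_sets, r_threshold = r_threshold,
                 flatness_threshold = flatness_threshold,
                 monotone_threshold = monotone_threshold),
            class = "drs_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Fields present in the file override the defaults of
#' [default_run_config()].
#'
#' @param path YAML file.
#' @return A `drs_run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# write a file atomically: temp file in the same directory, then rename
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, per probe: synthetic dataset generation, per-wavelength
#' statistical tests, significant-band extraction, cross-validated
#' PLS-KNN classification (for the selected bands, each individual
#' band, any user-supplied band sets and the full grid), and
#' chromophore/scattering attribution of the full-grid PLS loadings.
#' Writes `report.csv`, `bands_<probe>.json`, `pvalues_<probe>.csv`,
#' `attribution_<probe>.csv`, `loadings_<probe>.csv` and
#' `manifest.json` (configuration hash, seed, stage row counts) into
#' `out_dir`; all files are written atomically.
#'
#' @param config A `drs_run_config` (or YAML path).
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with per-probe results (`dataset` is not
#'   retained) and the report data frame.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  grid <- seq(350, 1920, by = config$grid_step)
  fw <- forward_model_config(grid = grid)
  lib <- chromophore_library()
  report <- NULL
  results <- list()
  counts <- list()

  for (pi in seq_along(config$probes)) {
    probe_name <- config$probes[pi]
    probe <- probe_geometry(probe_name)
    say("[%s] simulating %d patients x %d sites/class", probe_name,
        config$n_patients, config$sites_per_patient)
    pop <- population_spec(contrast = config$contrast,
                           n_patients = config$n_patients,
                           sites_per_patient = config$sites_per_patient,
                           seed = config$seed + pi)
    set <- simulate_dataset(pop, probe, fw, lib)
    counts[[probe_name]] <- nrow(set$spectra)

    say("[%s] per-wavelength tests on %d wavelengths", probe_name,
        length(grid))
    tests <- wavelength_tests(set)
    write_atomic(function(p) utils::write.csv(tests, p, row.names = FALSE),
                 file.path(out_dir, sprintf("pvalues_%s.csv", probe_name)))

    bands <- select_bands(tests, alpha = config$alpha,
                          min_run = config$min_run,
                          max_gap = config$max_gap)
    write_atomic(function(p) write_bands_json(bands, p),
                 file.path(out_dir, sprintf("bands_%s.json", probe_name)))
    say("[%s] %d significant band(s)", probe_name, nrow(bands$bands))

    # band sets evaluated through the identical protocol
    sets_to_run <- list()
    if (nrow(bands$bands) > 0) {
      sets_to_run[["selected bands"]] <- bands
      if (nrow(bands$bands) > 1)
        for (r in seq_len(nrow(bands$bands)))
          sets_to_run[[sprintf("%g-%g nm", bands$bands$lo[r],
                               bands$bands$hi[r])]] <-
            c(bands$bands$lo[r], bands$bands$hi[r])
    }
    for (nm in names(config$band_sets))
      sets_to_run[[nm]] <- do.call(rbind, config$band_sets[[nm]])
    sets_to_run[["full grid"]] <- c(min(grid), max(grid))

    for (bi in seq_along(sets_to_run)) {
      say("[%s] cross-validating band set '%s'", probe_name,
          names(sets_to_run)[bi])
      # narrow bands on coarse grids can hold fewer wavelengths than
      # the requested component count; cap rather than abort the run
      bmat <- as_band_matrix(sets_to_run[[bi]])
      n_cols <- sum(vapply(grid, function(w)
        any(w >= bmat[, 1] & w <= bmat[, 2]), logical(1)))
      k_eff <- min(config$k_components, n_cols)
      if (k_eff < config$k_components)
        say("[%s] band set '%s': reducing components to %d (only %d wavelengths)",
            probe_name, names(sets_to_run)[bi], k_eff, n_cols)
      cv <- cross_validate(set, sets_to_run[[bi]],
                           k_components = k_eff,
                           k_nn = config$k_nn,
                           iterations = config$iterations,
                           seed = config$seed + 100 + bi,
                           leakage_free = config$leakage_free)
      s <- cv$summary
      report <- rbind(report, data.frame(
        probe = probe_name, band_set = names(sets_to_run)[bi],
        sensitivity = s$mean[1], sensitivity_sd = s$sd[1],
        specificity = s$mean[2], specificity_sd = s$sd[2],
        accuracy = s$mean[3], accuracy_sd = s$sd[3],
        auc = s$mean[4], auc_sd = s$sd[4]))
    }

    say("[%s] attribution of full-grid loadings", probe_name)
    sc <- fit_scaling(set$spectra)
    full_model <- fit_pls(apply_scaling(set$spectra, sc), set$labels,
                          config$k_components, wavelengths = set$wavelengths)
    attr_m <- attribution_matrix(full_model, lib,
                                 r_threshold = config$r_threshold,
                                 flatness_threshold = config$flatness_threshold,
                                 monotone_threshold = config$monotone_threshold)
    write_atomic(function(p) utils::write.csv(
      data.frame(component = rownames(attr_m), unclass(attr_m)[, ]),
      p, row.names = FALSE),
      file.path(out_dir, sprintf("attribution_%s.csv", probe_name)))
    write_atomic(function(p) export_loadings(full_model, p),
                 file.path(out_dir, sprintf("loadings_%s.csv", probe_name)))

    results[[probe_name]] <- list(tests = tests, bands = bands,
                                  attribution = attr_m, model = full_model)
  }

  write_atomic(function(p) utils::write.csv(report, p, row.names = FALSE),
               file.path(out_dir, "report.csv"))

  cfg_yaml <- yaml::as.yaml(unclass(config))
  manifest <- list(
    config_md5 = md5_string(cfg_yaml),
    seed = config$seed,
    n_spectra = counts,
    n_wavelengths = length(grid),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  write_atomic(function(p) jsonlite::write_json(manifest, p,
                                                auto_unbox = TRUE),
               file.path(out_dir, "manifest.json"))
  say("pipeline finished in %.1f s", manifest$elapsed_sec)
  invisible(list(report = report, results = results, manifest = manifest))
}

md5_string <- function(x) {
  tmp <- tempfile()
  writeLines(x, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}
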