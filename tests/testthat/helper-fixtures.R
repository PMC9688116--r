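# shared fixtures: coarse analysis grids and small simulated cohorts

coarse_grid <- seq(350, 1920, by = 5)
tiny_grid <- seq(350, 1920, by = 25)

make_set <- function(contrast = "default", n_patients = 20, sites = 10,
                     seed = 7, probe = "short_SDD", grid = coarse_grid) {
  simulate_dataset(
    population_spec(contrast = contrast, n_patients = n_patients,
                    sites_per_patient = sites, seed = seed),
    probe_geometry(probe),
    forward_model_config(grid = grid))
}

# minimal stand-in for a fitted PLS model, for loading-interpretation
# tests where only the loading curves matter
fake_pls <- function(loadings, wavelengths) {
  loadings <- as.matrix(loadings)
  structure(list(n_components = ncol(loadings), loadings = loadings,
                 wavelengths = wavelengths),
            class = "drs_pls")
}

flat_spectrum <- function(value, wl = seq(350, 1920, by = 10),
                          kind = "reflectance") {
  spectrum(wl, rep(value, length(wl)), kind = kind)
}
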