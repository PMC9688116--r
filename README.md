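# drspipe

Diffuse reflectance spectroscopy (DRS) measures the light that re-emerges
from tissue after internal scattering and absorption. Because absorption is
set by the tissue's chromophores — deoxyhemoglobin (Hb), oxyhemoglobin
(HbO₂), water and lipid — and scattering by its microstructure, a broadband
reflectance spectrum (350–1920 nm) carries enough biochemical contrast to
discriminate colorectal mucosa from tumor at the probe tip, without staining
or excision. `drspipe` implements a complete, tested analysis pipeline for
this problem, aimed at biomedical-optics and chemometrics researchers who
need a reproducible reference implementation of the classification protocol
and of the loading-interpretation step that links classifier features back
to tissue biochemistry.

## What the package computes

* **Preprocessing.** Reflectance from raw spectrometer counts,
  `R(λ) = (1/ρ_ref) · (I_tissue − I_bg) / (I_ref − I_bg)`, and merging of
  the visible (350–1140 nm) and NIR/SWIR (1090–1920 nm) spectrometer
  readings into one broadband spectrum by a linear 101-point blend across
  the 1090–1140 nm overlap.
* **Band selection.** At every wavelength, Anderson–Darling and Lilliefors
  tests gate a pooled-variance Student *t*-test (Wilcoxon rank-sum
  fallback when normality is rejected); maximal contiguous runs with
  *p* < 0.001 become candidate wavelength bands.
* **Classification.** Per-wavelength scaling to [−1, +1], single-response
  PLS (mucosa = −1, tumor = +1) with four components, then weighted
  10-nearest-neighbor classification (squared-inverse-distance votes),
  evaluated by 20 iterations of stratified two-fold cross-validation;
  sensitivity, specificity, accuracy and rank-based AUC are reported as
  mean ± SD over iterations.
* **Interpretation.** PLS component loadings are ranked by regional
  amplitude and matched, band by band, against the chromophore absorption
  library; flat monotone loading segments in the 600–1350 nm
  low-absorption window are attributed to scattering. The result is the
  conventional components × {scattering, Hb, HbO₂, MetHb, water, lipid}
  feature matrix, with an evidence record behind every mark.
* **Synthetic data.** Since clinical DRS datasets are rarely deposited,
  the package ships a physics-based generator: tissue compositions drawn
  from a hierarchical (patient → site) log-normal population model are
  pushed through a diffusion-approximation forward model at the probe's
  source–detector separation (630 µm or 2500 µm) and corrupted with
  detector noise, yielding labeled two-probe cohorts with realistic class
  contrast and variance structure.

## Worked example

```r
library(drspipe)

# a synthetic cohort: 20 patients, 10 sites per class, short-SDD probe
pop <- population_spec(n_patients = 20, sites_per_patient = 10, seed = 7)
set <- simulate_dataset(pop, probe_geometry("short_SDD"),
                        forward_model_config(grid = seq(350, 1920, by = 5)))
set
#> <drs_spectra_set> short_SDD: 400 spectra (200 mucosa / 200 tumor), 20 patients, 315 wavelengths 350-1920 nm

# statistically significant wavelength bands (p < 0.001)
bands <- select_bands(wavelength_tests(set))
bands
#> <drs_band_set> alpha = 0.001, 3 band(s)
#>   350-475 nm
#>   510-595 nm
#>   605-1920 nm

# cross-validated PLS-KNN classification on those bands
cross_validate(set, bands, seed = 42)
#> <drs_cv_report> short_SDD | bands: 350-475 nm, 510-595 nm, 605-1920 nm | 4-component PLS, 10-NN
#>   sensitivity  (93.3 +/- 0.8)%
#>   specificity  (96.3 +/- 1.1)%
#>   accuracy     (94.8 +/- 0.6)%
#>   auc          0.987 +/- 0.003

# which chromophores drive each PLS component?
sc <- fit_scaling(set$spectra)
model <- fit_pls(apply_scaling(set$spectra, sc), set$labels, 4,
                 wavelengths = set$wavelengths)
attribution_matrix(model)
#>       vis_scatter nir_scatter    Hb HbO2 MetHb water lipid
#> PLSC1       FALSE       FALSE  TRUE TRUE FALSE  TRUE  TRUE
#> PLSC2       FALSE       FALSE  TRUE TRUE FALSE  TRUE  TRUE
#> PLSC3        TRUE        TRUE  TRUE TRUE FALSE  TRUE FALSE
#> PLSC4        TRUE       FALSE FALSE TRUE FALSE  TRUE  TRUE
```

Reading the output: the *t*-test recovers the hemoglobin Soret/Q-band
region and the broad NIR contrast planted by the generator's class
difference (tumor: doubled blood content, lower StO₂, more water, less
lipid, more scattering); classification on the selected bands reaches
~95 % accuracy on this synthetic cohort; and the first PLS component's
loadings carry hemoglobin and water signatures — blood-borne contrast
dominates, as expected for this tissue pair.

The same stages run end to end, with outputs written to disk
(`report.csv`, `bands_*.json`, `attribution_*.csv`, `loadings_*.csv`,
`manifest.json`), via

```r
run_pipeline(default_run_config(seed = 7), out_dir = "run1")
```

or from a shell through the thin CLI wrapper
`Rscript inst/cli/drspipe.R run --config inst/extdata/example-config.yaml --out run1`.

## Package layout

| | |
|---|---|
| `R/spectrum.R`, `R/reflectance.R`, `R/spectra_set.R` | spectra, reflectance computation, merging, tabular I/O |
| `R/chromophores.R` | absorption library, tissue optical properties |
| `R/forward_model.R`, `R/synthetic.R` | diffusion forward model, cohort generator |
| `R/band_selection.R` | normality-gated per-wavelength tests, band extraction |
| `R/pls.R`, `R/classify.R` | scaling, PLS, weighted KNN, cross-validation |
| `R/interpretation.R` | loading amplitude profiles and attribution |
| `R/pipeline.R` | orchestration, configuration, manifest |
| `vignettes/drs-pipeline.Rmd` | methods and design notes |
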