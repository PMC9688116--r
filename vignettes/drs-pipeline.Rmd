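---
title: "Methods: diffuse reflectance classification of colorectal tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffuse reflectance classification of colorectal tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the measurement

Diffuse reflectance spectroscopy (DRS) sends broadband light into tissue
through an optical fiber and collects, at a fixed source–detector
distance (SDD), the fraction that re-emerges after multiple scattering.
Absorption along the photon paths is dominated by a handful of
chromophores — deoxyhemoglobin (Hb), oxyhemoglobin (HbO₂), water and
lipid — while scattering reflects cell and organelle microstructure.
Colorectal tumors differ from normal mucosa in blood content, blood
oxygenation (StO₂), hydration, fat content and scattering, so their
reflectance spectra differ in characteristic, wavelength-localized ways.
Two probe geometries are modelled: a short-SDD probe (630 µm,
superficial sampling) and a long-SDD probe (2500 µm, deeper sampling).
Two spectrometers cover 350–1140 nm and 1090–1920 nm; their readings are
merged over the 1090–1140 nm overlap into one broadband spectrum.

The pipeline answers two questions: *which wavelength ranges
discriminate mucosa from tumor*, and *which chromophores are behind the
discrimination*.

# Preprocessing

**Reflectance.** Raw counts become reflectance via background
subtraction and normalization against a reflectance standard:
$$R(\lambda) = \frac{1}{\rho_{ref}}\cdot
\frac{I_{tissue}(\lambda)-I_{bg}(\lambda)}{I_{ref}(\lambda)-I_{bg}(\lambda)}.$$
`reference_reflectivity` defaults to 0.99, a typical value for sintered
PTFE standards; it is configurable as a scalar or a full spectrum.
Wavelengths where $I_{ref}-I_{bg}\le 0$ are reported as errors; values
driven below zero by noise are clipped to 0 with a warning, since
physical reflectance is non-negative.

**Merging.** Within the overlap the two spectra are interpolated onto
101 evenly spaced points indexed $i = 0..100$ and blended as
$R_i = [(100-i)\,R_{VIS,i} + i\,R_{NIR,i}]/100$, a linear crossfade that
is exact at both edges and therefore continuous. Outside the overlap the
respective spectrometer is used unchanged. The 101-point realization
makes the blend independent of the native pixel grids, which differ
between instruments; the merged spectrum is then resampled onto a
uniform output grid (1 nm by default).

**Grids.** The instrument profile defaults to a 1-nm grid over
350–1920 nm. The shipped analyses (tests, acceptance script) run on a
5-nm grid (315 wavelengths): per-wavelength statistics and PLS are
essentially unchanged by this decimation because all spectral features
of interest are tens of nanometres wide, and it keeps full replicate
studies fast. This is an analysis choice, not an instrument constraint.

# The synthetic study population

No public colorectal DRS dataset exists at this scale, so the generator
is a first-class module: every pipeline stage is developed and verified
against cohorts whose ground truth is known by construction.

**Composition model.** A tissue is described by total hemoglobin (in
arbitrary-but-consistent "blood units" — only class contrast matters
downstream, so absolute calibration is deliberately avoided), StO₂,
water and lipid volume fractions, and a reduced-scattering power law
$\mu_s'(\lambda) = a(\lambda/\lambda_0)^{-b}$ with $\lambda_0 = 500$ nm.
Mucosa defaults: tHb = 1, StO₂ = 0.75, water 0.65, lipid 0.10,
$a = 2\ \mathrm{mm^{-1}}$, $b = 1.2$ — mid-range values for
gastrointestinal soft tissue. The default tumor contrast is tHb ×2.0,
StO₂ → 0.60, water → 0.70, lipid → 0.05, $a$ ×1.2: directionally the
hypervascular, hypoxic, oedematous, fat-poor, more strongly scattering
phenotype reported for colorectal tumors. The magnitudes are generator
parameters fixed once, not claims about any cohort.

**Chromophore library.** Absorption curves are parametric sums of
Gaussian bands on smooth baselines with centres pinned at the
established peaks: HbO₂ 414/542/576 nm, Hb 433/556/757 nm, lipid
761/930/1210 nm plus the 1724/1760 nm double peak, water 970/1200/1440 nm
and the steep rise toward 1900 nm. Peak positions are the tested
contract; magnitudes are literature-scale approximations. The library is
also exported as `inst/extdata/chromophore_library_5nm.csv`.

**Hierarchy.** Each patient receives one multiplicative log-normal
effect (CV 0.2) shared by *both* tissue classes — mucosa and tumor are
sampled from the same resection specimen, so patient-level physiology
affects both — and each site an independent log-normal effect (CV 0.1).
This paired structure matters statistically: under a null contrast the
patient effect cancels between classes, so spectrum-wise per-wavelength
tests stay calibrated, while the marginal variance still shows the
clinical pattern that within-patient spread is comparable to (less than
twice) the pooled spread. Fractions are truncated to [0, 1] after the
multiplicative effects.

**Forward model.** Reflectance is the steady-state diffusion
approximation (Farrell-type) for a semi-infinite homogeneous medium,
evaluated at the probe SDD with refractive index 1.4, giving a local
reflectance in (0, 1] that decreases with absorption and with SDD. The
diffusion approximation is knowingly inaccurate where absorption rivals
scattering (the Soret band); this is accepted because the generator's
contract is statistical structure — monotone, chromophore-shaped class
contrast with realistic variance — not radiometric truth. An
`exp_attenuation` fallback model is available for degenerate regimes.

**Noise.** Each site's spectrum is the average of three noisy draws
(the triplicate-measurement convention of clinical DRS protocols), each
with 1 % multiplicative and 10⁻⁴ additive Gaussian noise, both tripled
above 1850 nm where detector sensitivity collapses.

**What the generator does *not* emulate** — and hence what passing
tests do not show about real data: instrument wavelength response and
etaloning, probe-pressure and contact artefacts, tissue heterogeneity
within a site (layers, blood pooling), histopathology label noise, and
unbalanced per-patient site counts. Results on synthetic cohorts
validate the *machinery*, not clinical performance.

# Band selection

At every wavelength the two class distributions are first gated for
normality: Anderson–Darling and Lilliefors tests in each class at
$\alpha_{norm} = 0.05$ (a conventional level; the gating step has no
stated level of its own). If neither test rejects in either class, a
two-sided pooled-variance Student *t*-test is applied — pooled rather
than Welch because the protocol names the classical Student test; Welch
is available via `two_sample_test` on pre-gated data. Otherwise the
two-sided Wilcoxon rank-sum test is used (exact for small untied
samples, normal approximation with tie correction otherwise).

Wavelengths with $p < 0.001$ are collected into maximal contiguous runs;
runs shorter than `min_run = 3` grid points are dropped and runs
separated by at most `max_gap = 0` points are merged. No
multiple-testing correction is applied by default — the per-wavelength
$p < 0.001$ rule *is* the protocol — and the spectral continuity of real
effects plus the run-length filter provide the practical false-positive
control (the null calibration test shows the realized rate is far below
0.5 % of wavelengths). Sub-splitting of one contiguous significant
region into several reported ranges is not algorithmically derivable;
user-specified band lists are therefore accepted everywhere a band set
is, and run through the identical classification protocol.

# Classification protocol

1. **Scaling.** Each wavelength column is mapped linearly onto
   [−1, +1] by its observed minimum and maximum (constant columns map
   to 0). This removes the orders-of-magnitude dynamic-range differences
   across 350–1920 nm so PLS weighs wavelengths comparably.
2. **PLS.** Single-response PLS (NIPALS) with the class coded
   mucosa = −1, tumor = +1. The first weight vector is proportional to
   the covariance of the centered spectra with the coded class;
   successive components come from deflated matrices, so scores are
   orthogonal. Four components are used, following the stopping rule
   "add components until the cross-validated accuracy gain drops below
   ~2 percentage points", which `select_n_components` implements; on
   default synthetic cohorts the rule selects 2–3, and the pipeline
   fixes 4 as its protocol constant.
3. **Weighted KNN.** 10 nearest neighbors in score space, each voting
   with weight $1/d^2$; the tumor posterior is tumor's share of the
   total vote weight. A zero-distance neighbor dominates (label copy).
   Posterior ties break toward tumor — the positive class in a
   screening context, where a false negative is costlier.
4. **Cross-validation.** Scaling and PLS are fit once on the *entire*
   dataset; each of 20 iterations then splits the spectra into two
   stratified equal halves, trains KNN on each half's scores and tests
   on the other, and averages the two folds. Reported figures are
   mean ± SD over the 20 iterations. Fitting the projection on all data
   is the reference protocol this package replicates; it leaks label
   information into the projection, which is why `leakage_free = TRUE`
   is provided to refit scaling and PLS inside every training fold when
   an honest generalization estimate is wanted. Stratification (not part
   of the reference wording, which only says equal halves) prevents
   degenerate folds with a missing class.
5. **Metrics.** Sensitivity (tumor = positive), specificity, accuracy
   in percent; AUC computed rank-based from the tumor posteriors,
   equivalent to the Mann–Whitney statistic with ties counted half.

# Loading interpretation

The amplitude profile ranks, per component, the mean absolute loading in
three macro-regions (350–600 nm, blood-dominated; 600–1350 nm, optical
window; 1350–1900 nm, water/lipid-dominated; ties break toward the lower
region).

Chromophore attribution operationalizes visual shape comparison, which
has no quantitative definition, as a declared surrogate:

* per chromophore, candidate bands where its features live (Hb/HbO₂
  380–450, 530–590, 740–780 nm; water 950–1000, 1150–1250, 1380–1500,
  1850–1920 nm; lipid 740–780, 1150–1250, 1700–1800 nm);
* within each band, the absolute Pearson correlation between the
  loading and the chromophore curve **after removing the band's linear
  baseline from both** — visual shape matching responds to the peaks and
  shoulders inside a band, not to its overall tilt, and per-wavelength
  scaling makes raw-curve correlations dominated by slow trends;
* an amplitude gate: the band's mean |loading| must reach half the
  component's median macro-region amplitude, so a shape match where the
  loading is essentially silent does not count. The gate is set at
  *half* the median region amplitude because [−1, +1] scaling flattens
  loading amplitude across the spectrum — discriminative bands stand
  out far less in loading magnitude than in covariance — and a gate at
  the full median would veto genuinely matched narrow bands
  (empirically, the hemoglobin Q-band) purely for being narrow;
* a mark requires correlation ≥ 0.6 in at least one band that passes
  the gate. Both metrics are sign-blind (PLS loadings have arbitrary
  sign).

The 740–780 nm band cannot separate Hb (757 nm) from lipid (761 nm) by
shape; hemoglobin absorption dominates tissue there, so a lipid mark
supported *only* by that band while Hb also matches in it is attributed
to Hb. Lipid marks backed by 1150–1250 or 1700–1800 nm are unaffected.

Scattering attribution: a loading that is relatively flat and monotone
across a low-absorption window (600–1000 nm "VIS", 1000–1350 nm "NIR")
is read as a scattering signature, since $\mu_s'$ is a smooth monotone
power law. Flatness is the normalized total variation
$TV = \sum|\Delta|/(\mathrm{range}+\varepsilon)$ of the 5-point-smoothed
loading ($TV = 1$ for any monotone curve; threshold 2 tolerates mild
ripple), monotonicity the larger one-signed fraction of first
differences (threshold 0.8). A `MetHb` column is kept in the output
matrix for layout fidelity with the conventional feature table; it is
always `FALSE` because methemoglobin is not in the default library
(the library interface accepts additional chromophores).

All thresholds (0.6, 0.8, 2, the half-median gate) are config-exposed
defaults, declared rather than hidden, and every positive cell in the
attribution matrix carries an evidence record (band, correlation,
amplitude, gate) in the result.

# Numerical and reproducibility choices

* Linear interpolation everywhere (`stats::approx`); resampling refuses
  to extrapolate.
* Degenerate two-sample inputs: zero pooled variance with equal means
  gives $p = 1$; with unequal means $p = 0$ is returned with a warning
  flagging the limit.
* `n_components` above the rank of the centered matrix is an error in
  `fit_pls`; the pipeline caps the component count at the number of
  wavelengths in a band set so narrow bands on coarse grids degrade
  gracefully instead of aborting a multi-band run.
* One global seed fans out to per-stage seeds by fixed offsets
  (simulation: seed + probe index; classification: seed + 100 + band-set
  index); a stored configuration reproduces a run bit-identically, and
  the manifest records the configuration hash and row counts. Output
  files are written atomically (temp file + rename).
* Problem sizes in the shipped checks: default cohorts of 47 patients ×
  15 sites per class per probe (1410 spectra) on the 5-nm grid;
  calibration experiments use 20 patients × 10 sites; replicate
  properties use 20 generations.

# Known limitations

* The diffusion forward model is quantitatively wrong in the Soret band
  and at short SDD in general; only the statistical structure of the
  generated data is contractual.
* Spectrum-wise (not patient-wise) cross-validation matches the
  reference protocol but optimistically weights within-patient
  generalization; the hierarchical generator keeps this honest only to
  the extent its variance ratios match clinical data.
* Chromophore attribution is a surrogate for expert visual judgement;
  its thresholds are declared but not clinically validated, and shared
  bands (Hb/lipid at 757/761 nm, water/lipid at 1150–1250 nm) are
  resolved by fixed dominance rules rather than unmixing, which is out
  of scope.
* The default library omits β-carotene, bile, bilirubin, ceroid,
  collagen, MetHb and melanin; they can be added through the same
  library interface if a study needs them.
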