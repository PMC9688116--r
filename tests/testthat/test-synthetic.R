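test_that("forward reflectance decreases with absorption and distance", {
  clear <- tissue_composition(total_hemoglobin = 0, water_fraction = 0,
                              lipid_fraction = 0)
  bloody <- tissue_composition(total_hemoglobin = 1, water_fraction = 0.6,
                               lipid_fraction = 0.1)
  cfg <- forward_model_config(grid = tiny_grid)
  short <- probe_geometry("short_SDD")
  long <- probe_geometry("long_SDD")

  r_clear <- forward_reflectance(clear, short, cfg)$values
  r_abs <- forward_reflectance(bloody, short, cfg)$values
  expect_true(all(r_clear > r_abs))

  r_long <- forward_reflectance(bloody, long, cfg)$values
  expect_true(all(r_abs > r_long))

  expect_true(all(r_abs > 0 & r_abs <= 1))
  expect_true(all(r_clear > 0 & r_clear <= 1))
})

test_that("diffusion forward model matches an independent evaluation", {
  # the same closed-form semi-infinite diffusion expression, written
  # out again step by step as an independent oracle
  oracle <- function(mua, musp, rho_mm, n) {
    mutr <- mua + musp
    D <- 1 / (3 * mutr)
    mueff <- sqrt(mua / D)
    z0 <- 1 / mutr
    rd <- -1.440 * n^-2 + 0.710 / n + 0.668 + 0.0636 * n
    A <- (1 + rd) / (1 - rd)
    zb <- 2 * A * D
    r1 <- sqrt(z0^2 + rho_mm^2)
    r2 <- sqrt((z0 + 2 * zb)^2 + rho_mm^2)
    term1 <- z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2
    term2 <- (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2
    (musp / mutr) / (4 * pi) * (term1 + term2)
  }
  for (case in list(c(0.05, 1.5, 0.63), c(0.4, 2.2, 0.63),
                    c(0.01, 0.9, 2.5))) {
    got <- drspipe:::farrell_reflectance(case[1], case[2], case[3], n = 1.4)
    expect_equal(got, oracle(case[1], case[2], case[3], 1.4),
                 tolerance = 1e-12)
  }
})

test_that("degenerate scattering is rejected; fallback model is monotone", {
  cfg <- forward_model_config(model = "exp_attenuation", grid = tiny_grid)
  comp <- tissue_composition()
  r <- forward_reflectance(comp, probe_geometry("short_SDD"), cfg)
  expect_true(all(r$values > 0 & r$values <= 1))
  expect_error(
    drspipe:::forward_values_raw(0.1, c(1, -1), probe_geometry("short_SDD"),
                                 forward_model_config(grid = c(400, 500))),
    "mu_s'")
})

test_that("tissue sampling reproduces the class mean at zero variance", {
  spec0 <- population_spec(patient_cv = 0, site_cv = 0)
  s <- sample_tissue("tumor", spec0)
  expect_equal(unlist(s[drspipe:::.var_params]),
               unlist(spec0$tumor[drspipe:::.var_params]),
               ignore_attr = TRUE)

  spec <- population_spec()
  set.seed(5); a <- sample_tissue("mucosa", spec)
  set.seed(5); b <- sample_tissue("mucosa", spec)
  expect_identical(a, b)
})

test_that("within-patient spread stays below twice the pooled spread", {
  # hierarchical draws: patient effect shared across that patient's
  # sites, site effect on top
  spec <- population_spec()
  set.seed(11)
  n_pat <- 50; n_site <- 20
  thb <- matrix(NA_real_, n_pat, n_site)
  for (p in seq_len(n_pat)) {
    zp <- rnorm(length(drspipe:::.var_params))
    for (s in seq_len(n_site))
      thb[p, s] <- sample_tissue("mucosa", spec,
                                 patient_z = zp)$total_hemoglobin
  }
  within_sd <- mean(apply(thb, 1, sd))
  pooled_sd <- sd(as.vector(thb))
  expect_lt(within_sd, 2 * pooled_sd)
})

test_that("a default cohort has the expected layout", {
  set <- make_set(n_patients = 47, sites = 15, seed = 3, grid = tiny_grid)
  expect_equal(nrow(set$spectra), 47 * 15 * 2)
  expect_equal(length(unique(set$patient_id)), 47)
  # labels balanced within every patient
  tab <- table(set$patient_id, set$labels)
  expect_true(all(tab == 15))
  expect_true(all(set$spectra >= 0 & set$spectra <= 1))
})

test_that("the generator is bit-reproducible under a fixed seed", {
  a <- make_set(seed = 21, n_patients = 5, sites = 4, grid = tiny_grid)
  b <- make_set(seed = 21, n_patients = 5, sites = 4, grid = tiny_grid)
  expect_identical(a$spectra, b$spectra)
  c2 <- make_set(seed = 22, n_patients = 5, sites = 4, grid = tiny_grid)
  expect_false(identical(a$spectra, c2$spectra))
})

test_that("clean spectra show hemoglobin Q-band reflectance minima", {
  g <- seq(500, 620, by = 1)
  comp <- tissue_composition(StO2 = 0.95)
  r <- forward_reflectance(comp, probe_geometry("short_SDD"),
                           forward_model_config(grid = g))$values
  minima <- g[which(diff(sign(diff(r))) == 2) + 1]
  expect_true(any(abs(minima - 542) <= 3))
  expect_true(any(abs(minima - 576) <= 3))
})

test_that("the dual-spectrometer path merges into a continuous spectrum", {
  out <- simulate_dataset(
    population_spec(n_patients = 3, sites_per_patient = 3, seed = 13),
    probe_geometry("short_SDD"),
    forward_model_config(grid = seq(350, 1920, by = 10)),
    return_raw = TRUE)
  expect_named(out, c("set", "vis", "nir"))
  expect_equal(nrow(out$set$spectra), 18)
  expect_true(all(is.finite(out$set$spectra)))
  expect_equal(max(out$vis$wavelengths), 1140)
  expect_equal(min(out$nir$wavelengths), 1090)
  # merged values inside the overlap lie between the two raw readings
  ov <- which(out$set$wavelengths >= 1090 & out$set$wavelengths <= 1140)
  vi <- match(out$set$wavelengths[ov], out$vis$wavelengths)
  ni <- match(out$set$wavelengths[ov], out$nir$wavelengths)
  for (r in 1:3) {
    lo <- pmin(out$vis$spectra[r, vi], out$nir$spectra[r, ni])
    hi <- pmax(out$vis$spectra[r, vi], out$nir$spectra[r, ni])
    expect_true(all(out$set$spectra[r, ov] >= lo - 1e-9))
    expect_true(all(out$set$spectra[r, ov] <= hi + 1e-9))
  }
})
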