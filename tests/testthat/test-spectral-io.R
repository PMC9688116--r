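test_that("spectrum construction enforces its invariants", {
  expect_error(spectrum(500, 1), "at least 2")
  expect_error(spectrum(c(500, 400), c(1, 1)), "strictly increasing")
  expect_error(spectrum(c(400, 400), c(1, 1)), "strictly increasing")
  expect_error(spectrum(c(400, 500), c(1, NA)), "finite")
  expect_error(spectrum(c(400, 500), 1), "equal length")
  s <- spectrum(c(400, 500), c(0.1, 0.2))
  expect_s3_class(s, "drs_spectrum")
  expect_equal(s$kind, "reflectance")
})

test_that("reflectance computation implements the reference-ratio formula", {
  wl <- seq(400, 700, by = 10)
  n <- length(wl)
  as_int <- function(v) spectrum(wl, rep(v, n), kind = "intensity")

  # tissue == reference, zero background, unit reflectivity -> R = 1
  r <- compute_reflectance(raw_measurement(as_int(900), as_int(0),
                                           as_int(900), 1))
  expect_equal(r$values, rep(1, n))
  expect_equal(r$kind, "reflectance")

  # tissue == background -> R = 0
  r0 <- compute_reflectance(raw_measurement(as_int(100), as_int(100),
                                            as_int(900), 1))
  expect_equal(r0$values, rep(0, n))

  # direct arithmetic: (500-100)/(900-100)/0.99
  r1 <- compute_reflectance(raw_measurement(as_int(500), as_int(100),
                                            as_int(900), 0.99))
  expect_equal(r1$values, rep(400 / 800 / 0.99, n), tolerance = 1e-12)
})

test_that("reflectance is invariant to a common detector gain", {
  wl <- seq(400, 700, by = 25)
  set.seed(1)
  tis <- runif(length(wl), 200, 600)
  bg <- runif(length(wl), 10, 50)
  ref <- runif(length(wl), 700, 1000)
  base <- compute_reflectance(raw_measurement(
    spectrum(wl, tis, "intensity"), spectrum(wl, bg, "intensity"),
    spectrum(wl, ref, "intensity"), 0.99))
  for (gain in c(0.5, 3, 17)) {
    scaled <- compute_reflectance(raw_measurement(
      spectrum(wl, gain * tis, "intensity"),
      spectrum(wl, gain * bg, "intensity"),
      spectrum(wl, gain * ref, "intensity"), 0.99))
    expect_equal(scaled$values, base$values, tolerance = 1e-12)
  }
})

test_that("non-positive reference signal errors name the wavelengths", {
  wl <- c(400, 500, 600)
  raw <- raw_measurement(spectrum(wl, c(5, 5, 5), "intensity"),
                         spectrum(wl, c(1, 10, 1), "intensity"),
                         spectrum(wl, c(9, 10, 9), "intensity"), 1)
  expect_error(compute_reflectance(raw), "500")
})

test_that("negative reflectance is clipped to zero with a warning", {
  wl <- c(400, 500)
  raw <- raw_measurement(spectrum(wl, c(1, 5), "intensity"),
                         spectrum(wl, c(3, 1), "intensity"),
                         spectrum(wl, c(9, 9), "intensity"), 1)
  expect_warning(r <- compute_reflectance(raw), "clipped")
  expect_equal(r$values[1], 0)
  expect_gt(r$values[2], 0)
})

test_that("spectrometer merging blends linearly across the overlap", {
  prof <- instrument_profile(grid_step = 1)
  wl_vis <- seq(350, 1140, by = 1)
  wl_nir <- seq(1090, 1920, by = 1)

  # equal inputs pass through unchanged
  m <- merge_spectra(spectrum(wl_vis, rep(0.4, length(wl_vis))),
                     spectrum(wl_nir, rep(0.4, length(wl_nir))), prof)
  expect_equal(m$values, rep(0.4, length(m$wavelengths)), tolerance = 1e-12)

  # vis = 1, nir = 0: endpoints keep the pure spectra, the midpoint is
  # the even blend, and the ramp is linear across the overlap
  m2 <- merge_spectra(spectrum(wl_vis, rep(1, length(wl_vis))),
                      spectrum(wl_nir, rep(0, length(wl_nir))), prof)
  at <- function(x) m2$values[m2$wavelengths == x]
  expect_equal(at(1090), 1)
  expect_equal(at(1140), 0)
  expect_equal(at(1115), 0.5, tolerance = 1e-12)
  ov <- m2$wavelengths >= 1090 & m2$wavelengths <= 1140
  expect_equal(m2$values[ov], 1 - (m2$wavelengths[ov] - 1090) / 50,
               tolerance = 1e-12)
  # continuity at the overlap edges on the shared grid
  expect_equal(at(1089), 1); expect_equal(at(1141), 0)
})

test_that("merged overlap values stay within the envelope of the inputs", {
  prof <- instrument_profile(grid_step = 1)
  set.seed(4)
  wl_vis <- seq(350, 1140, by = 1)
  wl_nir <- seq(1090, 1920, by = 1)
  for (rep in 1:5) {
    v <- 0.5 + 0.3 * sin(wl_vis / runif(1, 30, 120)) + runif(1, -0.1, 0.1)
    n <- 0.5 + 0.3 * cos(wl_nir / runif(1, 30, 120)) + runif(1, -0.1, 0.1)
    m <- merge_spectra(spectrum(wl_vis, v), spectrum(wl_nir, n), prof)
    ov <- m$wavelengths >= 1090 & m$wavelengths <= 1140
    vi <- approx(wl_vis, v, m$wavelengths[ov])$y
    ni <- approx(wl_nir, n, m$wavelengths[ov])$y
    expect_true(all(m$values[ov] >= pmin(vi, ni) - 1e-12))
    expect_true(all(m$values[ov] <= pmax(vi, ni) + 1e-12))
  }
})

test_that("merging requires coverage of the overlap", {
  prof <- instrument_profile()
  short_vis <- spectrum(seq(350, 1100, 1), rep(1, 751))
  nir <- spectrum(seq(1090, 1920, 1), rep(1, 831))
  expect_error(merge_spectra(short_vis, nir, prof), "overlap")
})

test_that("resampling is exact linear interpolation without extrapolation", {
  s <- spectrum(seq(400, 800, by = 10), seq(400, 800, by = 10))
  expect_equal(resample(s, s$wavelengths)$values, s$values)
  # a linear spectrum stays exact anywhere inside the span
  g <- sort(runif(50, 400, 800))
  expect_equal(resample(s, g)$values, g, tolerance = 1e-10)
  two <- spectrum(c(1090, 1140), c(0, 1))
  expect_equal(resample(two, c(1090, 1115, 1140))$values, c(0, 0.5, 1))
  expect_error(resample(s, c(350, 500)), "extrapolate")
})

test_that("spectra tables round-trip losslessly", {
  wl <- seq(500, 700, by = 50)
  set.seed(2)
  set <- labeled_spectra_set(matrix(runif(15), 3, 5), wl,
                             c("mucosa", "tumor", "mucosa"),
                             c("P01", "P01", "P02"), "short_SDD")
  path <- tempfile(fileext = ".csv")
  write_spectra_table(set, path)
  back <- read_spectra_table(path)
  expect_equal(back$spectra, set$spectra, ignore_attr = TRUE)
  expect_equal(as.character(back$labels), as.character(set$labels))
  expect_equal(back$patient_id, set$patient_id)
  expect_equal(back$probe, set$probe)
  expect_equal(back$wavelengths, set$wavelengths)
})

test_that("a study-scale table (2889 rows) round-trips with labels intact", {
  set.seed(3)
  n <- 2889
  wl <- seq(400, 1900, length.out = 12)
  labels <- sample(c("mucosa", "tumor"), n, replace = TRUE)
  set <- labeled_spectra_set(matrix(runif(n * 12), n, 12), wl, labels,
                             sprintf("P%02d", sample(47, n, TRUE)),
                             "long_SDD")
  path <- tempfile(fileext = ".csv")
  write_spectra_table(set, path)
  back <- read_spectra_table(path)
  expect_equal(nrow(back$spectra), n)
  expect_equal(as.character(back$labels), labels)
})

test_that("malformed tables fail with the offending row", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("label,patient_id,probe,500,600",
               "mucosa,P01,short_SDD,0.1,0.2",
               "tumor,P01,short_SDD,0.3"), path)
  expect_error(read_spectra_table(path), "row 3")

  writeLines(c("label,patient_id,probe,500,600",
               "polyp,P01,short_SDD,0.1,0.2"), path)
  expect_error(read_spectra_table(path), "polyp")

  writeLines(c("label,patient_id,probe,500,600",
               "mucosa,P01,short_SDD,0.1,abc"), path)
  expect_error(read_spectra_table(path), "non-numeric")
})
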