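#' Normality gate for one wavelength
#'
#' Decides whether the per-class reflectance distributions at one
#' wavelength may be treated as normal. Both the Anderson-Darling and
#' the Lilliefors (Kolmogorov-Smirnov with estimated parameters) tests
#' are run in each class; the wavelength is gated as non-normal as soon
#' as either test rejects in either class.
#'
#' @param groupA,groupB Numeric vectors of reflectance values of the
#'   two classes at one wavelength; each needs n >= 8.
#' @param alpha_norm Significance level of the normality tests.
#' @return A list with `decision` (`"normal"` or `"non-normal"`) and
#'   the per-class p-values of both tests.
#' @export
normality_gate <- function(groupA, groupB, alpha_norm = 0.05) {
  if (length(groupA) < 8 || length(groupB) < 8)
    stop("normality gating needs at least 8 observations per class")
  p <- c(ad_A = nortest::ad.test(groupA)$p.value,
         ad_B = nortest::ad.test(groupB)$p.value,
         lillie_A = nortest::lillie.test(groupA)$p.value,
         lillie_B = nortest::lillie.test(groupB)$p.value)
  list(decision = if (any(p < alpha_norm)) "non-normal" else "normal",
       p_values = p)
}

#' Two-sample test with normality-gated choice of statistic
#'
#' Applies a two-sided pooled-variance Student t-test when the gate
#' passed both classes as normal, and a two-sided Wilcoxon rank-sum
#' test otherwise (exact for small samples without ties, normal
#' approximation with tie correction for larger ones).
#'
#' Degenerate input with zero pooled variance returns p = 1 when the
#' group means are equal and p = 0 (flagged with a warning) when they
#' are not.
#'
#' @param groupA,groupB Numeric vectors, n >= 2 each.
#' @param gate `"normal"` or `"non-normal"` (e.g. the `decision` of
#'   [normality_gate()]).
#' @return The two-sided p-value.
#' @export
two_sample_test <- function(groupA, groupB, gate = "normal") {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("both groups need at least 2 observations")
  if (inherits(gate, "list")) gate <- gate$decision
  if (gate == "normal") {
    if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
      if (mean(groupA) == mean(groupB)) return(1)
      warning("zero pooled variance with unequal means: p-value is a 0-limit")
      return(0)
    }
    return(stats::t.test(groupA, groupB, var.equal = TRUE)$p.value)
  }
  n_min <- min(length(groupA), length(groupB))
  ties <- anyDuplicated(c(groupA, groupB)) > 0
  exact <- n_min <= 20 && !ties
  suppressWarnings(
    stats::wilcox.test(groupA, groupB, exact = exact, correct = TRUE)$p.value)
}

#' Per-wavelength two-class tests over a spectra set
#'
#' Runs the normality gate and the gated two-sample test at every
#' wavelength of the set, producing the per-wavelength p-value curve
#' that band selection thresholds.
#'
#' @param set A `drs_spectra_set` containing both classes.
#' @param alpha_norm Significance level of the normality gate.
#' @return A data frame of class `drs_wavelength_tests` with columns
#'   `wavelength`, `normal` (gate decision), `test_used`
#'   (`"t"`/`"wilcoxon"`) and `p_value`.
#' @export
wavelength_tests <- function(set, alpha_norm = 0.05) {
  stopifnot(inherits(set, "drs_spectra_set"))
  a_idx <- set$labels == "mucosa"
  b_idx <- set$labels == "tumor"
  if (!any(a_idx) || !any(b_idx))
    stop("both classes must be present")
  n_wl <- length(set$wavelengths)
  normal <- logical(n_wl)
  p_val <- numeric(n_wl)
  for (j in seq_len(n_wl)) {
    a <- set$spectra[a_idx, j]
    b <- set$spectra[b_idx, j]
    gate <- normality_gate(a, b, alpha_norm)$decision
    normal[j] <- gate == "normal"
    p_val[j] <- two_sample_test(a, b, gate)
  }
  structure(data.frame(wavelength = set$wavelengths,
                       normal = normal,
                       test_used = ifelse(normal, "t", "wilcoxon"),
                       p_value = p_val),
            class = c("drs_wavelength_tests", "data.frame"))
}

#' Extract contiguous significant wavelength bands
#'
#' Scans the per-wavelength p-value curve for maximal runs of
#' consecutive grid points with `p < alpha`. Runs separated by at most
#' `max_gap` non-significant grid points are merged; runs with fewer
#' than `min_run` points are dropped.
#'
#' @param tests A [wavelength_tests()] result, or any data frame with
#'   `wavelength` and `p_value` columns.
#' @param alpha Significance threshold (default 0.001, the selection
#'   rule of the pipeline).
#' @param min_run Minimum run length in grid points.
#' @param max_gap Maximum non-significant gap (grid points) bridged
#'   when merging adjacent runs.
#' @return An object of class `drs_band_set`: a list with `bands` (a
#'   data frame of `lo`, `hi` in nm, ordered and disjoint) and `alpha`.
#'   An empty band set is allowed.
#' @export
select_bands <- function(tests, alpha = 0.001, min_run = 3, max_gap = 0) {
  stopifnot(all(c("wavelength", "p_value") %in% names(tests)))
  wl <- tests$wavelength
  sig <- tests$p_value < alpha
  runs <- significant_runs(sig, min_run, max_gap)
  bands <- if (nrow(runs) == 0) {
    data.frame(lo = numeric(0), hi = numeric(0))
  } else {
    data.frame(lo = wl[runs$start], hi = wl[runs$end])
  }
  structure(list(bands = bands, alpha = alpha), class = "drs_band_set")
}

# run-length scan over a logical vector: maximal TRUE runs, gap
# merging, then minimum-length filtering
significant_runs <- function(sig, min_run, max_gap) {
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  runs <- data.frame(start = starts[keep], end = ends[keep])
  if (nrow(runs) > 1 && max_gap > 0) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= max_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs[runs$end - runs$start + 1L >= min_run, , drop = FALSE]
}

#' @export
print.drs_band_set <- function(x, ...) {
  cat(sprintf("<drs_band_set> alpha = %g, %d band(s)\n", x$alpha,
              nrow(x$bands)))
  if (nrow(x$bands))
    cat(paste(sprintf("  %g-%g nm", x$bands$lo, x$bands$hi),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize / read a band set as JSON
#'
#' @param bands A `drs_band_set`.
#' @param path Output path.
#' @return `path` invisibly; `read_bands_json` returns a
#'   `drs_band_set`.
#' @export
write_bands_json <- function(bands, path) {
  stopifnot(inherits(bands, "drs_band_set"))
  jsonlite::write_json(
    list(alpha = bands$alpha,
         bands = unname(apply(bands$bands, 1, function(r) c(r[1], r[2]),
                              simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bands_json
#' @export
read_bands_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- x$bands
  if (length(b) == 0) {
    bands <- data.frame(lo = numeric(0), hi = numeric(0))
  } else {
    if (is.list(b)) b <- do.call(rbind, b)
    if (is.null(dim(b))) b <- matrix(b, ncol = 2, byrow = TRUE)
    bands <- data.frame(lo = b[, 1], hi = b[, 2])
  }
  structure(list(bands = bands, alpha = x$alpha), class = "drs_band_set")
}
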