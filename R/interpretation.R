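#' Mean absolute loading amplitude per wavelength region
#'
#' For each PLS component, computes the mean absolute loading inside
#' each named region and ranks the regions by that amplitude
#' (descending; ties break toward the lower-wavelength region). High
#' amplitude in a region means the wavelengths there carry much of the
#' class discrimination for that component.
#'
#' @param model A [fit_pls()] model with `wavelengths` attached.
#' @param regions Named list of `c(lo, hi)` intervals (nm). The
#'   defaults split the spectrum at 600 and 1350 nm: the blood-
#'   absorption-dominated visible region, the optical window, and the
#'   water/lipid-dominated SWIR region.
#' @return An object of class `drs_amplitude_profile`: per component a
#'   data frame of region means and the region ranking.
#' @export
amplitude_profile <- function(model,
                              regions = list("350-600 nm" = c(350, 600),
                                             "600-1350 nm" = c(600, 1350),
                                             "1350-1900 nm" = c(1350, 1900))) {
  stopifnot(inherits(model, "drs_pls"))
  wl <- model$wavelengths
  if (is.null(wl)) stop("model carries no wavelength grid")
  if (is.null(names(regions)))
    names(regions) <- vapply(regions, function(r)
      sprintf("%g-%g nm", r[1], r[2]), character(1))
  per_comp <- lapply(seq_len(model$n_components), function(a) {
    load <- abs(model$loadings[, a])
    means <- vapply(regions, function(r) {
      idx <- wl >= r[1] & wl <= r[2]
      if (!any(idx))
        stop(sprintf("region %g-%g nm contains no grid points", r[1], r[2]))
      mean(load[idx])
    }, numeric(1))
    lo <- vapply(regions, `[`, numeric(1), 1L)
    ranking <- names(regions)[order(-means, lo)]
    list(mean_abs_loading = means, ranking = ranking)
  })
  names(per_comp) <- paste0("PLSC", seq_len(model$n_components))
  structure(per_comp, class = "drs_amplitude_profile")
}

#' Attribute PLS loading shape to chromophores
#'
#' Operationalizes visual shape comparison between loading curves and
#' chromophore absorption spectra: for each component and chromophore
#' the absolute Pearson correlation between the loading and the
#' chromophore's absorption curve is computed inside each of the
#' chromophore's characteristic bands, after removing each band's
#' linear baseline from both curves — so the match reflects the
#' chromophore's characteristic band structure (peaks, shoulders)
#' rather than an overall tilt, mirroring what visual shape comparison
#' responds to. The chromophore is marked for the component when
#' (a) the best band correlation reaches `r_threshold` and (b) that
#' band's mean absolute loading reaches half the component's median
#' regional amplitude (the median of the mean absolute loadings over
#' the `amp_regions` macro-regions) — so a good shape match in a
#' region where the loading is essentially silent does not count.
#' Both metrics are sign-blind, respecting the sign indeterminacy of
#' PLS loadings.
#'
#' The 740-780 nm band is shared between the Hb 757 nm and lipid
#' 761 nm peaks and cannot distinguish them by shape alone. Since
#' hemoglobin absorption (and typically concentration) dominates there,
#' a lipid mark supported only by that band while Hb also matches in it
#' is attributed to Hb and the lipid mark is dropped; lipid marks backed
#' by its 1150-1250 or 1700-1800 nm bands are unaffected.
#'
#' @param model A [fit_pls()] model with wavelengths.
#' @param lib A [chromophore_library()].
#' @param bands An [attribution_bands()] object.
#' @param r_threshold Minimum absolute correlation (default 0.6).
#' @param amp_regions Macro-regions used for the amplitude gate.
#' @return An object of class `drs_attribution`: a logical components
#'   x chromophores matrix plus an `evidence` data frame recording,
#'   per component/chromophore/band, the correlation, amplitude and
#'   gate values behind every decision.
#' @export
attribute_chromophores <- function(model, lib = chromophore_library(),
                                   bands = attribution_bands(),
                                   r_threshold = 0.6,
                                   amp_regions = list(c(350, 600),
                                                      c(600, 1350),
                                                      c(1350, 1900))) {
  stopifnot(inherits(model, "drs_pls"),
            inherits(bands, "drs_attribution_bands"))
  wl <- model$wavelengths
  if (is.null(wl)) stop("model carries no wavelength grid")
  chroms <- names(bands$chromophores)
  n_comp <- model$n_components
  marks <- matrix(FALSE, n_comp, length(chroms),
                  dimnames = list(paste0("PLSC", seq_len(n_comp)), chroms))
  evidence <- NULL

  band_index <- function(b) {
    idx <- which(wl >= b[1] & wl <= b[2])
    if (length(idx) < 5)
      stop(sprintf("band %g-%g nm has fewer than 5 grid points", b[1], b[2]))
    idx
  }

  detrend <- function(v, x) stats::lm.fit(cbind(1, x), v)$residuals

  for (a in seq_len(n_comp)) {
    load <- model$loadings[, a]
    # amplitude gate: half the median regional mean-|loading|
    reg_means <- vapply(amp_regions, function(r) {
      idx <- wl >= r[1] & wl <= r[2]
      if (!any(idx)) NA_real_ else mean(abs(load[idx]))
    }, numeric(1))
    gate_base <- stats::median(reg_means, na.rm = TRUE)
    if (!is.finite(gate_base) || gate_base <= 0) gate_base <- mean(abs(load))
    amp_gate <- gate_base / 2

    hit_bands <- stats::setNames(vector("list", length(chroms)), chroms)
    for (ch in chroms) {
      for (b in bands$chromophores[[ch]]) {
        idx <- band_index(b)
        curve <- absorption(ch, wl[idx], lib)$values
        r <- suppressWarnings(stats::cor(detrend(load[idx], wl[idx]),
                                         detrend(curve, wl[idx])))
        if (is.na(r)) r <- 0
        amp <- mean(abs(load[idx]))
        hit <- abs(r) >= r_threshold && amp >= amp_gate
        if (hit) {
          marks[a, ch] <- TRUE
          hit_bands[[ch]] <- c(hit_bands[[ch]], list(b))
        }
        evidence <- rbind(evidence, data.frame(
          component = a, chromophore = ch, lo = b[1], hi = b[2],
          abs_r = abs(r), mean_abs_loading = amp,
          amplitude_gate = amp_gate, marked = hit))
      }
    }
    # Hb-over-lipid disambiguation in the shared 740-780 nm band
    if (marks[a, "lipid"] && marks[a, "Hb"]) {
      lipid_only_757 <- all(vapply(hit_bands[["lipid"]],
                                   function(b) b[2] <= 800, logical(1)))
      hb_757 <- any(vapply(hit_bands[["Hb"]],
                           function(b) b[1] >= 700 && b[2] <= 800,
                           logical(1)))
      if (lipid_only_757 && hb_757) marks[a, "lipid"] <- FALSE
    }
  }
  structure(list(marks = marks, evidence = evidence,
                 r_threshold = r_threshold), class = "drs_attribution")
}

#' Attribute flat monotone loading segments to scattering
#'
#' A loading that is relatively flat and monotone across a
#' low-absorption window is read as a scattering signature (reduced
#' scattering follows a smooth monotone power law in wavelength).
#' Flatness is measured as the normalized total variation
#' `TV = sum(|diff|) / (range + eps)` of the lightly smoothed loading
#' in the window (a monotone curve has TV = 1); monotonicity as the
#' larger one-signed fraction of first differences after 5-point
#' smoothing. The window is marked when `TV <= flatness_threshold`
#' and the monotone fraction reaches `monotone_threshold`.
#'
#' @param model A [fit_pls()] model with wavelengths.
#' @param bands An [attribution_bands()] (its `scattering` windows are
#'   used).
#' @param flatness_threshold Maximum normalized total variation
#'   (default 2).
#' @param monotone_threshold Minimum monotone fraction (default 0.8).
#' @return A logical matrix components x `c("vis_scatter",
#'   "nir_scatter")` with an `evidence` attribute of the metric values.
#' @export
attribute_scattering <- function(model, bands = attribution_bands(),
                                 flatness_threshold = 2,
                                 monotone_threshold = 0.8) {
  stopifnot(inherits(model, "drs_pls"))
  wl <- model$wavelengths
  if (is.null(wl)) stop("model carries no wavelength grid")
  windows <- bands$scattering
  out <- matrix(FALSE, model$n_components, 2,
                dimnames = list(paste0("PLSC", seq_len(model$n_components)),
                                c("vis_scatter", "nir_scatter")))
  evidence <- NULL
  for (a in seq_len(model$n_components)) {
    load <- model$loadings[, a]
    for (w in seq_along(windows)) {
      b <- windows[[w]]
      idx <- which(wl >= b[1] & wl <= b[2])
      seg <- smooth_5pt(load[idx])
      tv <- sum(abs(diff(seg))) / (diff(range(seg)) + 1e-12)
      d <- diff(seg)
      mono <- max(mean(d >= 0), mean(d <= 0))
      hit <- tv <= flatness_threshold && mono >= monotone_threshold
      out[a, w] <- hit
      evidence <- rbind(evidence, data.frame(
        component = a, window = colnames(out)[w], lo = b[1], hi = b[2],
        total_variation = tv, monotone_fraction = mono, marked = hit))
    }
  }
  attr(out, "evidence") <- evidence
  out
}

# centered 5-point running mean with shrinking edges
smooth_5pt <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - 2); hi <- min(n, i + 2)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Combine chromophore and scattering attribution into a feature matrix
#'
#' Produces the components-by-features boolean matrix summarizing which
#' scattering windows and chromophores contribute to each PLS
#' component. A `MetHb` column is retained for layout fidelity with
#' the conventional feature-table format but stays `FALSE` with the
#' default library, which does not include methemoglobin.
#'
#' @inheritParams attribute_chromophores
#' @inheritParams attribute_scattering
#' @return An object of class `drs_attribution_matrix` with columns
#'   `vis_scatter`, `nir_scatter`, `Hb`, `HbO2`, `MetHb`, `water`,
#'   `lipid` and an `evidence` attribute.
#' @export
attribution_matrix <- function(model, lib = chromophore_library(),
                               bands = attribution_bands(),
                               r_threshold = 0.6, flatness_threshold = 2,
                               monotone_threshold = 0.8) {
  chrom <- attribute_chromophores(model, lib, bands, r_threshold)
  scat <- attribute_scattering(model, bands, flatness_threshold,
                               monotone_threshold)
  m <- cbind(scat,
             Hb = chrom$marks[, "Hb"], HbO2 = chrom$marks[, "HbO2"],
             MetHb = FALSE,
             water = chrom$marks[, "water"], lipid = chrom$marks[, "lipid"])
  structure(m, class = c("drs_attribution_matrix", class(m)),
            evidence = list(chromophores = chrom$evidence,
                            scattering = attr(scat, "evidence")))
}

#' Export PLS loadings to a delimited table
#'
#' Writes one row per wavelength with raw and absolute loading values
#' per component (so a 4-component model yields 8 value columns).
#'
#' @param model A [fit_pls()] model with wavelengths.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
export_loadings <- function(model, path) {
  stopifnot(inherits(model, "drs_pls"))
  wl <- model$wavelengths
  if (is.null(wl)) stop("model carries no wavelength grid")
  df <- data.frame(wavelength = wl)
  for (a in seq_len(model$n_components)) {
    df[[sprintf("PLSC%d", a)]] <- model$loadings[, a]
    df[[sprintf("PLSC%d_abs", a)]] <- abs(model$loadings[, a])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
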