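#' Per-wavelength [-1, +1] scaling
#'
#' Learns, per wavelength column, the observed minimum and maximum and
#' maps values linearly so the fitting data spans exactly \[-1, +1\]
#' column-wise: `x' = 2 (x - min) / (max - min) - 1`. This removes the
#' large dynamic-range differences between wavelengths so the PLS step
#' weighs every wavelength on a comparable scale. Constant columns map
#' to 0.
#'
#' @param X Numeric matrix (sites x wavelengths), >= 2 rows.
#' @return An object of class `drs_scaling` holding per-column `min`
#'   and `max`.
#' @export
fit_scaling <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("scaling needs at least 2 rows")
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "drs_scaling")
}

#' @rdname fit_scaling
#' @param params A `drs_scaling` fit.
#' @return `apply_scaling` returns the rescaled matrix.
#' @export
apply_scaling <- function(X, params) {
  stopifnot(inherits(params, "drs_scaling"))
  X <- as.matrix(X)
  if (ncol(X) != length(params$min))
    stop("column count does not match the scaling fit")
  rng <- params$max - params$min
  out <- sweep(X, 2, params$min, `-`)
  ok <- rng > 0
  out[, ok] <- 2 * sweep(out[, ok, drop = FALSE], 2, rng[ok], `/`) - 1
  out[, !ok] <- 0
  out
}

# class labels coded for single-response PLS: mucosa -1, tumor +1
code_labels <- function(labels) {
  labels <- factor(as.character(labels), levels = c("mucosa", "tumor"))
  ifelse(labels == "tumor", 1, -1)
}

#' Fit a single-response PLS model (NIPALS)
#'
#' Partial least squares with the class coded as a single response
#' (mucosa = -1, tumor = +1), fit by iterative deflation. The first
#' weight vector is proportional to the covariance of the centered
#' predictor matrix with the coded response; successive components are
#' extracted from the deflated matrix, so score vectors are mutually
#' orthogonal. The per-component loading vectors are the quantities
#' interpreted against chromophore absorption spectra downstream.
#'
#' @param X Numeric matrix (sites x wavelengths), typically already
#'   passed through [apply_scaling()].
#' @param labels Class labels (`"mucosa"`/`"tumor"`) or a numeric
#'   response.
#' @param n_components Number of components; must not exceed the rank
#'   of the centered matrix.
#' @param wavelengths Optional wavelength grid attached to the model
#'   for loading interpretation.
#' @return An object of class `drs_pls` with elements `weights`,
#'   `loadings` (columns = components), `scores`, `y_loadings`,
#'   `centers`, `rotation` (projection matrix for new data),
#'   `coefficients` and `wavelengths`.
#' @export
fit_pls <- function(X, labels, n_components = 4, wavelengths = NULL) {
  X <- as.matrix(X)
  y <- if (is.numeric(labels)) as.numeric(labels) else code_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (n_components < 1) stop("n_components must be >= 1")
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  y_mean <- mean(y)
  yc <- y - y_mean
  rk <- qr(Xc)$rank
  if (n_components > rk)
    stop(sprintf("n_components (%d) exceeds the rank of the matrix (%d)",
                 n_components, rk))
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    w <- w / sqrt(sum(w^2))
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xd, t_a) / tt
    q[a] <- sum(yd * t_a) / tt
    Xd <- Xd - t_a %*% t(p_a)
    yd <- yd - q[a] * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
  }
  rotation <- W %*% solve(crossprod(P, W))
  coef <- rotation %*% q
  structure(list(n_components = n_components, weights = W, loadings = P,
                 scores = Tm, y_loadings = q, centers = centers,
                 y_mean = y_mean, rotation = rotation, coefficients = coef,
                 wavelengths = wavelengths),
            class = "drs_pls")
}

#' Project data onto the score space of a fitted PLS model
#'
#' Centers the data with the training column means and applies the
#' model's rotation. Projecting the training matrix reproduces the
#' stored scores.
#'
#' @param model A [fit_pls()] model.
#' @param X Matrix with the same column count as the training data.
#' @return Score matrix (rows x `n_components`).
#' @export
project <- function(model, X) {
  stopifnot(inherits(model, "drs_pls"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$centers))
    stop("column count does not match the fitted model")
  sweep(X, 2, model$centers) %*% model$rotation
}

# fitted response of the PLS regression (used for the OLS-equivalence
# check and for the component-count rule)
predict_pls_response <- function(model, X) {
  drop(project(model, X) %*% model$y_loadings) + model$y_mean
}

#' Choose the number of PLS components by the accuracy-increment rule
#'
#' Computes cross-validated classification accuracy `acc(k)` for
#' k = 1..`max_k` components and returns the smallest k at which adding
#' the next component improves accuracy by less than `threshold`
#' percentage points. This mirrors the stopping rule used to fix the
#' default of four components; the default pipeline takes k = 4 without
#' re-running this search.
#'
#' @param X Scaled predictor matrix.
#' @param labels Class labels.
#' @param k_nn Neighbors for the KNN classifier used in the inner
#'   evaluation.
#' @param iterations Cross-validation iterations per k.
#' @param threshold Accuracy-increment threshold in percentage points
#'   (default 2).
#' @param max_k Largest k examined.
#' @param seed RNG seed for the inner splits.
#' @return A list with `k` (the selected count) and `accuracy` (the
#'   acc(k) sequence, %).
#' @export
select_n_components <- function(X, labels, k_nn = 10, iterations = 5,
                                threshold = 2, max_k = 10, seed = 1) {
  X <- as.matrix(X)
  rk <- qr(sweep(X, 2, colMeans(X)))$rank
  max_k <- min(max_k, rk)
  acc <- vapply(seq_len(max_k), function(k) {
    m <- fit_pls(X, labels, k)
    cv <- cv_protocol(m$scores, factor(as.character(labels),
                                       levels = c("mucosa", "tumor")),
                      k_nn = k_nn, iterations = iterations, seed = seed)
    mean(cv$accuracy)
  }, numeric(1))
  apply_increment_rule(acc, threshold)
}

# the stopping rule itself, separated so it can be applied to any
# accuracy sequence: smallest k with acc(k+1) - acc(k) < threshold
apply_increment_rule <- function(acc, threshold = 2) {
  k <- length(acc)
  for (i in seq_len(length(acc) - 1)) {
    if (acc[i + 1] - acc[i] < threshold) { k <- i; break }
  }
  list(k = k, accuracy = acc)
}
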