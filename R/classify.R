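#' Weighted k-nearest-neighbor prediction in PLS score space
#'
#' Classifies query points by the k nearest training points in
#' Euclidean distance, each voting with weight 1/d^2 (squared inverse
#' distance). The tumor posterior is the tumor share of the total
#' vote weight. A zero-distance neighbor dominates: the posterior is
#' then taken over the zero-distance neighbors only (label copy).
#' Posterior ties break toward tumor, the positive class.
#'
#' @param train_scores Numeric matrix of training scores.
#' @param train_labels Labels (`"mucosa"`/`"tumor"`) for the training
#'   rows.
#' @param query_scores Matrix of query scores with the same number of
#'   columns.
#' @param k Number of neighbors (default 10); must not exceed the
#'   number of training rows.
#' @return A data frame with `posterior_tumor` and `predicted` per
#'   query row.
#' @export
knn_predict <- function(train_scores, train_labels, query_scores, k = 10) {
  train_scores <- as.matrix(train_scores)
  query_scores <- as.matrix(query_scores)
  if (ncol(query_scores) != ncol(train_scores))
    stop("query and training scores must have the same dimension")
  n_train <- nrow(train_scores)
  if (k > n_train) stop("k must not exceed the number of training points")
  is_tumor <- as.character(train_labels) == "tumor"

  # squared Euclidean distances, query x train
  q2 <- rowSums(query_scores^2)
  t2 <- rowSums(train_scores^2)
  d2 <- outer(q2, t2, `+`) - 2 * tcrossprod(query_scores, train_scores)
  d2 <- pmax(d2, 0)

  post <- numeric(nrow(query_scores))
  for (i in seq_len(nrow(query_scores))) {
    ord <- order(d2[i, ])[seq_len(k)]
    dd <- d2[i, ord]
    zero <- dd < .Machine$double.eps
    if (any(zero)) {
      post[i] <- mean(is_tumor[ord][zero])
    } else {
      w <- 1 / dd
      post[i] <- sum(w[is_tumor[ord]]) / sum(w)
    }
  }
  data.frame(posterior_tumor = post,
             predicted = factor(ifelse(post >= 0.5, "tumor", "mucosa"),
                                levels = c("mucosa", "tumor")))
}

#' Classification performance metrics
#'
#' Sensitivity is the true-positive rate with tumor as the positive
#' class, specificity the true-negative rate on mucosa, accuracy the
#' overall fraction correct; all three are reported in percent. The
#' AUC is rank-based (equivalent to the Mann-Whitney statistic on the
#' tumor posterior): the probability that a random tumor site receives
#' a higher tumor posterior than a random mucosa site, counting ties
#' as one half.
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param posterior Tumor posterior per observation (for the AUC).
#' @return A list with `sensitivity`, `specificity`, `accuracy` (in %)
#'   and `auc`.
#' @export
confusion_metrics <- function(truth, predicted, posterior) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (!any(truth == "tumor") || !any(truth == "mucosa"))
    stop("both classes must be present in the truth labels")
  tp <- sum(truth == "tumor" & predicted == "tumor")
  fn <- sum(truth == "tumor" & predicted == "mucosa")
  tn <- sum(truth == "mucosa" & predicted == "mucosa")
  fp <- sum(truth == "mucosa" & predicted == "tumor")
  r <- rank(posterior)
  n1 <- sum(truth == "tumor")
  n0 <- sum(truth == "mucosa")
  auc <- (sum(r[truth == "tumor"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       accuracy = 100 * (tp + tn) / length(truth),
       auc = auc)
}

# stratified split of indices into two equal halves
stratified_halves <- function(labels) {
  fold1 <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold1 <- c(fold1, sample(idx, floor(length(idx) / 2)))
  }
  fold1
}

# repeated two-fold CV of weighted KNN on a fixed score matrix
cv_protocol <- function(scores, labels, k_nn = 10, iterations = 20,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(iteration = seq_len(iterations), sensitivity = NA_real_,
                    specificity = NA_real_, accuracy = NA_real_,
                    auc = NA_real_)
  n <- nrow(scores)
  for (it in seq_len(iterations)) {
    half1 <- stratified_halves(labels)
    half2 <- setdiff(seq_len(n), half1)
    fold_m <- lapply(list(c(train = 1, test = 2), c(train = 2, test = 1)),
                     function(spec) {
      tr <- if (spec["train"] == 1) half1 else half2
      te <- if (spec["test"] == 1) half1 else half2
      pred <- knn_predict(scores[tr, , drop = FALSE], labels[tr],
                          scores[te, , drop = FALSE], k = k_nn)
      confusion_metrics(labels[te], pred$predicted, pred$posterior_tumor)
    })
    for (m in c("sensitivity", "specificity", "accuracy", "auc"))
      out[[m]][it] <- mean(vapply(fold_m, `[[`, numeric(1), m))
  }
  out
}

#' Cross-validated PLS-KNN tissue classification
#'
#' Runs the full classification protocol on a labeled spectra set:
#' per-wavelength \[-1, +1\] scaling, single-response PLS with
#' `k_components` components, then weighted KNN evaluated by
#' `iterations` repetitions of stratified two-fold cross-validation
#' (each iteration randomly splits the spectra into two equal halves,
#' uses each half to train and the other to test, and averages the two
#' folds). Reported figures are the mean and standard deviation over
#' iterations.
#'
#' By default scaling and PLS are fit once on the entire dataset
#' before cross-validation — the protocol under which the reference
#' performance figures of this analysis style are defined. Set
#' `leakage_free = TRUE` to refit scaling and PLS inside each training
#' fold instead, which gives an honest generalization estimate at the
#' price of deviating from that protocol.
#'
#' @param set A `drs_spectra_set` with both classes.
#' @param bands Optional bands ([select_bands()] result or explicit
#'   `lo`/`hi` intervals) to restrict the wavelengths first.
#' @param k_components PLS components (default 4).
#' @param k_nn KNN neighbors (default 10).
#' @param iterations Cross-validation iterations (default 20).
#' @param seed RNG seed for the splits.
#' @param leakage_free Refit scaling and PLS per training fold.
#' @return An object of class `drs_cv_report`: per-iteration metrics,
#'   a mean +/- SD summary, the band description and (unless
#'   `leakage_free`) the full-data PLS model used.
#' @export
cross_validate <- function(set, bands = NULL, k_components = 4, k_nn = 10,
                           iterations = 20, seed = 1,
                           leakage_free = FALSE) {
  stopifnot(inherits(set, "drs_spectra_set"))
  band_label <- "full grid"
  if (!is.null(bands)) {
    b <- as_band_matrix(bands)
    band_label <- paste(sprintf("%g-%g nm", b[, 1], b[, 2]), collapse = ", ")
    set <- restrict_dataset(set, bands)
  }
  labels <- set$labels
  if (!all(table(labels) >= 2)) stop("both classes must be present")
  set.seed(seed)

  model <- NULL
  if (!leakage_free) {
    sc <- fit_scaling(set$spectra)
    Xs <- apply_scaling(set$spectra, sc)
    model <- fit_pls(Xs, labels, k_components, wavelengths = set$wavelengths)
    metrics <- cv_protocol(model$scores, labels, k_nn = k_nn,
                           iterations = iterations, seed = NULL)
  } else {
    n <- nrow(set$spectra)
    metrics <- data.frame(iteration = seq_len(iterations),
                          sensitivity = NA_real_, specificity = NA_real_,
                          accuracy = NA_real_, auc = NA_real_)
    for (it in seq_len(iterations)) {
      half1 <- stratified_halves(labels)
      half2 <- setdiff(seq_len(n), half1)
      fold_m <- lapply(list(list(tr = half1, te = half2),
                            list(tr = half2, te = half1)), function(f) {
        sc <- fit_scaling(set$spectra[f$tr, , drop = FALSE])
        Xtr <- apply_scaling(set$spectra[f$tr, , drop = FALSE], sc)
        Xte <- apply_scaling(set$spectra[f$te, , drop = FALSE], sc)
        m <- fit_pls(Xtr, labels[f$tr], k_components)
        pred <- knn_predict(m$scores, labels[f$tr], project(m, Xte), k = k_nn)
        confusion_metrics(labels[f$te], pred$predicted, pred$posterior_tumor)
      })
      for (m in c("sensitivity", "specificity", "accuracy", "auc"))
        metrics[[m]][it] <- mean(vapply(fold_m, `[[`, numeric(1), m))
    }
  }

  summ <- data.frame(
    metric = c("sensitivity", "specificity", "accuracy", "auc"),
    mean = vapply(c("sensitivity", "specificity", "accuracy", "auc"),
                  function(m) mean(metrics[[m]]), numeric(1)),
    sd = vapply(c("sensitivity", "specificity", "accuracy", "auc"),
                function(m) stats::sd(metrics[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(metrics = metrics, summary = summ, bands = band_label,
                 probe = set$probe, k_components = k_components,
                 k_nn = k_nn, leakage_free = leakage_free, model = model),
            class = "drs_cv_report")
}

#' @export
print.drs_cv_report <- function(x, ...) {
  cat(sprintf("<drs_cv_report> %s | bands: %s | %d-component PLS, %d-NN%s\n",
              x$probe, x$bands, x$k_components, x$k_nn,
              if (x$leakage_free) " (leakage-free)" else ""))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (s$metric[i] == "auc") {
      cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
    } else {
      cat(sprintf("  %-12s (%.1f +/- %.1f)%%\n", s$metric[i], s$mean[i],
                  s$sd[i]))
    }
  }
  invisible(x)
}
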