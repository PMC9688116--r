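test_that("weighted KNN follows the squared-inverse-distance vote", {
  # zero-distance neighbor copies its label with posterior 1
  train <- matrix(c(0, 1, 3), ncol = 1)
  labs <- c("mucosa", "mucosa", "tumor")
  hit <- knn_predict(train, labs, matrix(3), k = 3)
  expect_equal(hit$posterior_tumor, 1)
  expect_equal(as.character(hit$predicted), "tumor")

  # hand-computed 1-D example: weights 1/4, 1, 1 at distances 2, 1, 1
  p <- knn_predict(train, labs, matrix(2), k = 3)
  expect_equal(p$posterior_tumor, 1 / 2.25, tolerance = 1e-12)
  expect_equal(as.character(p$predicted), "mucosa")

  expect_error(knn_predict(train, labs, matrix(1), k = 5), "k must not")
})

test_that("KNN posteriors agree with brute-force recomputation", {
  brute <- function(train, labs, q, k) {
    d2 <- colSums((t(train) - q)^2)
    ord <- order(d2)[1:k]
    dd <- d2[ord]
    tum <- labs[ord] == "tumor"
    if (any(dd == 0)) return(mean(tum[dd == 0]))
    sum((1 / dd)[tum]) / sum(1 / dd)
  }
  set.seed(61)
  for (i in 1:50) {
    n <- sample(15:40, 1)
    d <- sample(2:4, 1)
    train <- matrix(rnorm(n * d), n, d)
    labs <- sample(c("mucosa", "tumor"), n, replace = TRUE,
                   prob = c(0.5, 0.5))
    q <- rnorm(d)
    k <- sample(3:min(10, n), 1)
    got <- knn_predict(train, labs, matrix(q, 1), k)$posterior_tumor
    expect_equal(got, brute(train, labs, q, k), tolerance = 1e-12)
  }
})

test_that("confusion metrics count correctly and AUC is the pairwise rate", {
  truth <- c(rep("tumor", 10), rep("mucosa", 10))
  pred <- c(rep("tumor", 8), rep("mucosa", 2),
            rep("mucosa", 9), "tumor")
  post <- c(seq(0.6, 0.9, length.out = 10), seq(0.1, 0.4, length.out = 10))
  m <- confusion_metrics(truth, pred, post)
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 90)
  expect_equal(m$accuracy, 85)
  expect_equal(m$auc, 1) # posteriors perfectly ranked

  expect_error(confusion_metrics(rep("tumor", 5), rep("tumor", 5), 1:5),
               "both classes")

  # rank-based AUC equals the brute-force pairwise count
  set.seed(62)
  for (i in 1:30) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    post <- c(round(rnorm(n1, 0.6, 0.3), 2), round(rnorm(n0, 0.4, 0.3), 2))
    truth <- c(rep("tumor", n1), rep("mucosa", n0))
    pred <- ifelse(post >= 0.5, "tumor", "mucosa")
    got <- confusion_metrics(truth, pred, post)$auc
    pairs <- outer(post[1:n1], post[n1 + 1:n0],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(got, mean(pairs), tolerance = 1e-12)
  }
})

test_that("perfectly separated classes classify perfectly with zero spread", {
  set.seed(63)
  n <- 60
  X <- rbind(matrix(rnorm(n, 0, 0.2), ncol = 2),
             matrix(rnorm(n, 10, 0.2), ncol = 2))
  set <- labeled_spectra_set(X, c(500, 600),
                             rep(c("mucosa", "tumor"), each = n / 2),
                             sprintf("P%d", rep(1:6, 10)), "short_SDD")
  cv <- cross_validate(set, k_components = 1, iterations = 20, seed = 3)
  s <- cv$summary
  expect_equal(s$mean[s$metric == "accuracy"], 100)
  expect_equal(s$sd[s$metric == "accuracy"], 0)
  expect_equal(s$mean[s$metric == "auc"], 1)
})

test_that("cross-validation is reproducible and stable across seeds", {
  set <- make_set(n_patients = 10, sites = 6, seed = 64, grid = coarse_grid)
  a <- cross_validate(set, c(530, 590), seed = 7)
  b <- cross_validate(set, c(530, 590), seed = 7)
  expect_identical(a$metrics, b$metrics)
  c2 <- cross_validate(set, c(530, 590), seed = 8)
  sa <- a$summary; sc <- c2$summary
  expect_lt(abs(sa$mean[3] - sc$mean[3]),
            2 * (sa$sd[3] + sc$sd[3]) + 1)
})

test_that("null-contrast data classifies at chance level", {
  set <- make_set(contrast = "null", n_patients = 20, sites = 10,
                  seed = 65, grid = coarse_grid)
  cv <- cross_validate(set, seed = 9)
  acc <- cv$summary$mean[cv$summary$metric == "accuracy"]
  expect_gt(acc, 45)
  expect_lt(acc, 55)
})

test_that("scaling, PLS and projection are invariant to row order", {
  set <- make_set(n_patients = 8, sites = 5, seed = 66, grid = tiny_grid)
  sc <- fit_scaling(set$spectra)
  m <- fit_pls(apply_scaling(set$spectra, sc), set$labels, 3)
  set.seed(67)
  perm <- sample(nrow(set$spectra))
  sc_p <- fit_scaling(set$spectra[perm, ])
  m_p <- fit_pls(apply_scaling(set$spectra[perm, ], sc_p),
                 set$labels[perm], 3)
  expect_equal(m_p$scores, m$scores[perm, ], tolerance = 1e-8)
  expect_equal(abs(m_p$loadings), abs(m$loadings), tolerance = 1e-8)
})

test_that("leakage-free mode runs the fold-refit protocol", {
  set <- make_set(n_patients = 10, sites = 6, seed = 68, grid = coarse_grid)
  cv <- cross_validate(set, c(530, 590), iterations = 5, seed = 10,
                       leakage_free = TRUE)
  expect_null(cv$model)
  expect_equal(nrow(cv$metrics), 5)
  expect_true(all(cv$metrics$accuracy >= 0 & cv$metrics$accuracy <= 100))
})
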