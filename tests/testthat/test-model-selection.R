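# Stratified folds, RMSE, classification metrics, the one-SE rule, and the
# cross-validation driver.

test_that("stratified folds cover all indices, respect strata, and are seeded", {
  g <- rep(c("a", "b"), each = 10)
  folds <- stratified_kfold(g, k = 10, seed = 1)
  expect_length(folds, 10)
  expect_identical(sort(unlist(folds)), 1:20)
  for (f in folds) {
    expect_length(f, 2)
    expect_setequal(g[f], c("a", "b"))
  }
  expect_identical(stratified_kfold(g, 10, seed = 1), folds)
  expect_false(identical(stratified_kfold(g, 10, seed = 2), folds))
  # per-fold proportions within one member for unbalanced strata
  g2 <- rep(c(0, 1), c(23, 17))
  folds2 <- stratified_kfold(g2, k = 5, seed = 3)
  counts <- sapply(folds2, function(f) sum(g2[f] == 1))
  expect_lte(diff(range(counts)), 1)
  expect_error(stratified_kfold(g, k = 40), "between")
})

test_that("multivariate RMSE matches the brute-force pooled formula", {
  expect_equal(multivariate_rmse(diag(3), diag(3)), 0)
  expect_equal(multivariate_rmse(matrix(0, 4, 2), matrix(1, 4, 2)), 1)
  set.seed(2)
  Y <- matrix(rnorm(12), 4, 3)
  Yh <- matrix(rnorm(12), 4, 3)
  expect_equal(multivariate_rmse(Y, Yh), sqrt(sum((Y - Yh)^2) / 12))
  expect_error(multivariate_rmse(Y, Yh[, 1:2]), "shape")
})

test_that("classification metrics match hand-evaluated confusion arithmetic", {
  # perfectly separated
  m <- classification_metrics(c(-2, -1, 1, 2), c(0, 0, 1, 1))
  expect_equal(unlist(m), c(accuracy = 1, sensitivity = 1, specificity = 1, auc = 1))
  # TP = 3, FN = 1, TN = 4, FP = 2
  scores <- c(1, 1, 1, -1, -1, -1, -1, -1, 1, 1)
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  m2 <- classification_metrics(scores, truth)
  expect_equal(m2$sensitivity, 0.75)
  expect_equal(m2$specificity, 2 / 3, tolerance = 1e-12)
  expect_equal(m2$accuracy, 0.7)
  # single-class truth: NA, not an error
  m3 <- classification_metrics(c(1, 2), c(1, 1))
  expect_true(is.na(m3$auc))
  expect_true(is.na(m3$specificity))
})

test_that("rank AUC is ~0.5 under independence and matches pROC", {
  set.seed(3)
  scores <- rnorm(1e4)
  truth <- rbinom(1e4, 1, 0.4)
  auc <- classification_metrics(scores, truth)$auc
  expect_lt(abs(auc - 0.5), 0.02)
  skip_if_not_installed("pROC")
  set.seed(4)
  s2 <- rnorm(200); t2 <- rbinom(200, 1, 0.5)
  s2[t2 == 1] <- s2[t2 == 1] + 0.8
  auc2 <- classification_metrics(s2, t2)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(t2, s2, quiet = TRUE, direction = "<")))
  expect_equal(auc2, ref, tolerance = 1e-10)
})

test_that("one-SE rule matches hand cases and a brute-force oracle", {
  expect_equal(select_k_one_se(c(1.00, 0.90, 0.89), c(0.05, 0.05, 0.05)), 2)
  expect_equal(select_k_one_se(c(1, 0.8, 0.6), c(0, 0, 0)), 3)
  oracle <- function(m, s) {
    ks <- which.min(m)
    thr <- m[ks] + s[ks]
    for (k in seq_along(m)) if (m[k] <= thr) return(k)
  }
  set.seed(5)
  for (i in 1:100) {
    m <- runif(sample(3:12, 1), 0.5, 2)
    s <- runif(length(m), 0, 0.3)
    expect_identical(select_k_one_se(m, s), oracle(m, s))
  }
  expect_error(select_k_one_se(numeric(0), numeric(0)), "empty")
})

test_that("noiseless latent-structure data drive CV RMSE to zero at the true K", {
  # X and Y share two exact latent components (noise-free forward model)
  set.seed(6)
  n <- 60; p <- 10; L <- 2
  scores <- matrix(rnorm(n * L), n, L) %*% diag(c(2, 1))
  P <- qr.Q(qr(matrix(rnorm(p * L), p, L)))
  C <- matrix(rnorm(2 * L), 2, L)
  X <- scores %*% t(P)
  Y <- scores %*% t(C)
  cv <- cross_validate(X, Y, Kmax = 5, folds = 5, model = "euclidean", seed = 7)
  expect_lt(cv$rmse_mean[2], 1e-8)
  expect_equal(cv$k_selected, 2)
  expect_equal(dim(cv$rmse_by_fold), c(5, 5))
})

test_that("cross-validation is deterministic given the seed", {
  ds <- generate_rpls_dataset(n = 30, R = 4, L = 1, q = 2, seed = 8)
  cv1 <- cross_validate(ds$X, ds$Y, Kmax = 3, folds = 5, model = "riemannian", seed = 9)
  cv2 <- cross_validate(ds$X, ds$Y, Kmax = 3, folds = 5, model = "riemannian", seed = 9)
  expect_identical(cv1$rmse_by_fold, cv2$rmse_by_fold)
  expect_identical(cv1$k_selected, cv2$k_selected)
})

test_that("held-out data never leak into a fold's fitted model", {
  ds <- generate_rpls_dataset(n = 30, R = 4, L = 1, q = 2, seed = 10)
  cv <- cross_validate(ds$X, ds$Y, Kmax = 2, folds = 5, model = "riemannian",
                       seed = 11, store_fits = TRUE)
  # perturb every subject held out in fold 1, refit: fold-1 model unchanged
  idx <- cv$folds[[1]]
  X2 <- ds$X
  for (i in idx) X2[[i]] <- exp_map(X2[[i]], make_sym(4, 0.5, seed = i))
  Y2 <- ds$Y
  Y2[idx, ] <- Y2[idx, ] + 5
  cv2 <- cross_validate(X2, Y2, Kmax = 2, folds = 5, model = "riemannian",
                        seed = 11, store_fits = TRUE)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$fits[[1]]$coefficients, cv2$fits[[1]]$coefficients)
})

test_that("group classification and pooled R-squared are produced at the selected K", {
  set.seed(12)
  sim <- generate_group_timeseries(n = 40, R = 5, T = 120, effect_size = 0.4, seed = 13)
  X <- lapply(sim$timeseries, correlation_matrix)
  Y <- data.frame(group = sim$phenotypes$group, age = sim$phenotypes$age)
  cv <- cross_validate(X, Y, Kmax = 3, folds = 5, model = "riemannian",
                       seed = 14, group = "group")
  expect_s3_class(cv$classification, "tbl_df")
  expect_equal(nrow(cv$classification), 5)
  expect_true(all(cv$classification$accuracy >= 0 & cv$classification$accuracy <= 1,
                  na.rm = TRUE))
  expect_lt(cv$r2_pooled, 1)
  # SE definition: sd over folds / sqrt(folds)
  expect_equal(cv$rmse_se, apply(cv$rmse_by_fold, 2, sd) / sqrt(5))
})

test_that("raw and fisher comparator models run and differ from the riemannian fit", {
  ds <- generate_rpls_dataset(n = 30, R = 4, L = 1, q = 2, seed = 15)
  # scale into correlation-like range so atanh is defined
  Xc <- lapply(ds$X, function(A) stats::cov2cor(A))
  cv_raw <- cross_validate(Xc, ds$Y, Kmax = 2, folds = 5, model = "raw", seed = 16)
  cv_fis <- cross_validate(Xc, ds$Y, Kmax = 2, folds = 5, model = "fisher", seed = 16)
  cv_rie <- cross_validate(Xc, ds$Y, Kmax = 2, folds = 5, model = "riemannian", seed = 16)
  expect_false(identical(cv_raw$rmse_mean, cv_rie$rmse_mean))
  expect_false(identical(cv_raw$rmse_mean, cv_fis$rmse_mean))
})
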