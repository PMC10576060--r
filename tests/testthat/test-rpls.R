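# Vectorisation of symmetric tangents, the tNIPALS fit, Euclidean reduction,
# and prediction on the SPD manifold.

test_that("vectorisation length matches R(R+1)/2 for the study atlas sizes", {
  expect_length(vectorize_sym(diag(39)), 780)
  expect_length(vectorize_sym(diag(116)), 6786)
})

test_that("vectorize/unvectorize round-trip exactly and preserve the Frobenius product", {
  set.seed(1)
  for (R in c(3, 5, 8)) {
    S <- make_sym(R)
    # unscaled half-vectorisation inverts bit for bit; the sqrt(2) scaling
    # inverts to machine precision
    expect_identical(unvectorize_sym(vectorize_sym(S, 1), R, 1), S)
    expect_equal(unvectorize_sym(vectorize_sym(S), R), S, tolerance = 1e-14)
    v <- rnorm(R * (R + 1) / 2)
    expect_equal(vectorize_sym(unvectorize_sym(v, R), sqrt(2)), v, tolerance = 1e-14)
    U <- make_sym(R); V <- make_sym(R)
    expect_equal(sum(vectorize_sym(U) * vectorize_sym(V)), sum(U * V),
                 tolerance = 1e-12)
    expect_identical(unvectorize_sym(rep(0, R * (R + 1) / 2), R), matrix(0, R, R))
  }
  expect_error(unvectorize_sym(1:5, 4), "length")
  S <- matrix(rnorm(9), 3, 3)
  expect_error(vectorize_sym(S), "symmetric")
})

test_that("the coordinate index map matches the vectorisation order", {
  idx <- sym_vec_index(4, letters[1:4])
  S <- matrix(0, 4, 4)
  S[2, 3] <- S[3, 2] <- 5
  v <- vectorize_sym(S, scale_offdiag = 1)
  hit <- which(v == 5)
  expect_equal(idx$row[hit], 2)
  expect_equal(idx$col[hit], 3)
  expect_equal(idx$label[hit], "b--c")
  expect_equal(sum(idx$diagonal), 4)
})

test_that("tNIPALS with Euclidean blocks reduces exactly to Euclidean NIPALS", {
  d <- make_regression(50, 8, 3, noise_sd = 0.3, seed = 2)
  fit_r <- tnipals_fit(d$X, d$Y, K = 4)
  fit_e <- nipals_fit(d$X, d$Y, K = 4)
  expect_identical(fit_r$pls$weights, fit_e$weights)
  expect_identical(fit_r$pls$x_scores, fit_e$x_scores)
  expect_identical(fit_r$pls$coefficients, fit_e$coefficients)
  Xnew <- matrix(rnorm(5 * 8), 5, 8)
  expect_identical(rpls_predict(fit_r, Xnew), pls_predict(fit_e, Xnew))
})

test_that("noiseless single-component data: loading recovery and forward-model round trip", {
  ds <- generate_rpls_dataset(n = 60, R = 5, L = 1, q = 2,
                              noise_sd_x = 0, noise_sd_y = 0, seed = 3)
  fit <- tnipals_fit(ds$X, ds$Y, K = 1)
  w <- fit$pls$weights[, 1]
  truth <- vectorize_sym(ds$true_loadings[[1]])
  cosine <- sum(w * truth) / sqrt(sum(w^2) * sum(truth^2))
  expect_gte(abs(cosine), 0.99)
  pred <- rpls_predict(fit, ds$X)
  expect_lt(max(abs(pred - ds$Y)) / max(abs(ds$Y)), 1e-3)
  # predicting at the Frechet mean returns the mean response
  expect_equal(drop(rpls_predict(fit, list(fit$mu_X))), fit$pls$y_means,
               tolerance = 1e-8)
})

test_that("tangent scores inherit the orthogonality invariant", {
  ds <- generate_rpls_dataset(n = 40, R = 4, L = 2, q = 2, seed = 4)
  fit <- tnipals_fit(ds$X, ds$Y, K = 2)
  TtT <- crossprod(fit$pls$x_scores)
  expect_lt(max(abs(TtT - diag(diag(TtT)))), 1e-8)
})

test_that("loading-subspace recovery holds across seeded replicates", {
  cosines <- vapply(1:20, function(seed) {
    ds <- generate_rpls_dataset(n = 100, R = 6, L = 2, q = 2,
                                noise_sd_x = 0.02, noise_sd_y = 0.02, seed = seed)
    fit <- tnipals_fit(ds$X, ds$Y, K = 2)
    truth <- cbind(vectorize_sym(ds$true_loadings[[1]]),
                   vectorize_sym(ds$true_loadings[[2]]))
    subspace_mean_cosine(fit$pls$weights, truth)
  }, numeric(1))
  expect_gte(mean(cosines), 0.9)
})

test_that("whitened tangent coordinates make cross-validated RMSE congruence stable", {
  ds <- generate_rpls_dataset(n = 40, R = 4, L = 1, q = 2,
                              noise_sd_x = 0.05, noise_sd_y = 0.05, seed = 5)
  set.seed(6)
  G <- diag(4) + 0.3 * matrix(rnorm(16), 4, 4)
  XG <- lapply(ds$X, function(A) (G %*% A %*% t(G) + t(G %*% A %*% t(G))) / 2)
  cv1 <- cross_validate(ds$X, ds$Y, Kmax = 3, folds = 5, model = "riemannian",
                        seed = 7, whiten = TRUE)
  cv2 <- cross_validate(XG, ds$Y, Kmax = 3, folds = 5, model = "riemannian",
                        seed = 7, whiten = TRUE)
  expect_lt(max(abs(cv1$rmse_mean - cv2$rmse_mean)), 1e-4)
})

test_that("SPD-valued responses are predicted back on the manifold", {
  set.seed(8)
  Xs <- replicate(30, exp_map(diag(3), make_sym(3, 0.2)), simplify = FALSE)
  Ys <- lapply(Xs, function(A) exp_map(spd_power(A, 0.5), make_sym(3, 0.02)))
  fit <- tnipals_fit(Xs, Ys, K = 2)
  preds <- rpls_predict(fit, Xs[1:3])
  expect_true(all(vapply(preds, is_spd, logical(1))))
})
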