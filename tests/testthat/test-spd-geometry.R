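# Affine-invariant geometry: validation, matrix functions, Exp/Log maps,
# distance, and the Frechet mean.

test_that("SPD validation accepts SPD input and rejects asymmetric or indefinite input", {
  A <- make_spd(4, seed = 1)
  expect_true(is_spd(A))
  expect_false(is_spd(A - diag(4) * 10))        # indefinite
  bad <- A
  bad[1, 2] <- bad[1, 2] + 1                    # asymmetric
  expect_false(is_spd(bad))
  expect_error(spd_power(bad, 0.5), "symmetric")
  expect_error(geodesic_distance(A, make_spd(3, seed = 2)), "dimension")
})

test_that("spd_power matches closed forms and squares to the original", {
  expect_equal(spd_power(diag(2), 0.5), diag(2))
  expect_equal(spd_power(diag(c(4, 9)), 0.5), diag(c(2, 3)))
  for (seed in 1:5) {
    A <- make_spd(5, seed = seed)
    H <- spd_power(A, 0.5)
    expect_lt(max(abs(H %*% H - A)), 1e-10)
    expect_lt(max(abs(spd_power(A, -1) %*% A - diag(5))), 1e-10)
  }
})

test_that("affine metric is symmetric, positive, and congruence invariant", {
  A <- diag(2)
  expect_equal(affine_metric(A, diag(2), diag(2)), 2)
  set.seed(42)
  for (i in 1:10) {
    A <- random_spd(4)
    U <- make_sym(4)
    V <- make_sym(4)
    expect_equal(affine_metric(A, U, V), affine_metric(A, V, U))
    expect_gt(affine_metric(A, U, U), 0)
    G <- matrix(rnorm(16), 4, 4)
    expect_equal(
      affine_metric((G %*% A %*% t(G) + t(G %*% A %*% t(G))) / 2,
                    (G %*% U %*% t(G) + t(G %*% U %*% t(G))) / 2,
                    (G %*% V %*% t(G) + t(G %*% V %*% t(G))) / 2),
      affine_metric(A, U, V),
      tolerance = 1e-8
    )
  }
})

test_that("geodesic distance matches the eigenvalue closed form and is affine invariant", {
  A <- make_spd(4, seed = 3)
  expect_equal(geodesic_distance(A, A), 0, tolerance = 1e-10)
  # whitened eigenvalues (e^2, 1): log values (2, 0), norm 2
  expect_equal(geodesic_distance(diag(2), diag(c(exp(2), 1))), 2)
  set.seed(7)
  for (i in 1:10) {
    A <- random_spd(3)
    B <- random_spd(3)
    G <- matrix(rnorm(9), 3, 3)
    expect_equal(geodesic_distance(G %*% A %*% t(G), G %*% B %*% t(G)),
                 geodesic_distance(A, B), tolerance = 1e-8)
    expect_equal(geodesic_distance(A, B), geodesic_distance(B, A), tolerance = 1e-12)
  }
})

test_that("Exp and Log are mutually inverse and consistent with the distance", {
  set.seed(11)
  for (R in c(3, 6)) {
    for (i in 1:10) {
      A <- random_spd(R)
      U <- make_sym(R, sd = 1 / R)   # ||U|| moderate
      B <- exp_map(A, U)
      expect_true(is_spd(B))
      expect_lt(max(abs(log_map(A, B) - U)), 1e-8)
      B2 <- random_spd(R)
      expect_lt(max(abs(exp_map(A, log_map(A, B2)) - B2)), 1e-8)
      L <- log_map(A, B2)
      expect_equal(sqrt(affine_metric(A, L, L)), geodesic_distance(A, B2),
                   tolerance = 1e-8)
    }
  }
  A <- make_spd(4, seed = 5)
  expect_equal(exp_map(A, matrix(0, 4, 4)), A, tolerance = 1e-12)
  U <- make_sym(3, seed = 6)
  # independent spectral oracle for the identity-base case
  e <- eigen(U, symmetric = TRUE)
  expm_U <- e$vectors %*% diag(exp(e$values)) %*% t(e$vectors)
  expect_equal(exp_map(diag(3), U), expm_U, tolerance = 1e-10)
  expect_lt(max(abs(log_map(A, A))), 1e-10)
})

test_that("Frechet mean: single point, geodesic midpoint, commuting family", {
  A <- make_spd(4, seed = 8)
  fm1 <- frechet_mean(list(A))
  expect_true(fm1$converged)
  expect_equal(fm1$mean, A)

  B <- make_spd(4, seed = 9)
  fm2 <- frechet_mean(list(A, B))
  expect_true(fm2$converged)
  expect_lt(max(abs(fm2$mean - exp_map(A, 0.5 * log_map(A, B)))), 1e-6)

  # commuting diagonal family: geometric mean of the eigenvalues
  d1 <- c(1, 2, 4); d2 <- c(2, 1, 8); d3 <- c(4, 4, 2)
  fm3 <- frechet_mean(list(diag(d1), diag(d2), diag(d3)))
  expect_true(fm3$converged)
  expect_lt(max(abs(fm3$mean - diag(exp((log(d1) + log(d2) + log(d3)) / 3)))), 1e-6)

  expect_error(frechet_mean(list()), "nonempty")
})

test_that("Frechet mean is congruence equivariant and its objective is non-increasing", {
  set.seed(13)
  pts <- replicate(8, exp_map(make_spd(4), make_sym(4, 0.3)), simplify = FALSE)
  fm <- frechet_mean(pts)
  expect_true(fm$converged)
  expect_true(all(diff(fm$objective) <= 1e-8))
  G <- matrix(rnorm(16), 4, 4)
  ptsG <- lapply(pts, function(X) (G %*% X %*% t(G) + t(G %*% X %*% t(G))) / 2)
  fmG <- frechet_mean(ptsG)
  expect_lt(max(abs(fmG$mean - G %*% fm$mean %*% t(G))), 1e-6)
})

test_that("non-convergent Frechet mean is flagged, not an error", {
  set.seed(14)
  pts <- replicate(5, exp_map(diag(3), make_sym(3, 0.5)), simplify = FALSE)
  fm <- frechet_mean(pts, max_iter = 1L, tol = 1e-14)
  expect_false(fm$converged)
  expect_s3_class(fm, "frechet_mean")
})
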