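# Connectivity construction, regularisation, Fisher features, and
# network-level coefficient summaries.

test_that("correlation matrices are symmetric with unit diagonal and detect degenerate ROIs", {
  set.seed(1)
  ts <- matrix(rnorm(200 * 4), 200, 4)
  colnames(ts) <- paste0("r", 1:4)
  C <- correlation_matrix(ts)
  expect_equal(diag(C), setNames(rep(1, 4), paste0("r", 1:4)))
  expect_equal(C, t(C))
  # duplicated column gives off-diagonal 1
  ts2 <- cbind(a = ts[, 1], b = ts[, 1], c = ts[, 2])
  expect_equal(correlation_matrix(ts2)["a", "b"], 1)
  # independent columns at large T are near zero
  set.seed(2)
  big <- matrix(rnorm(1e4 * 3), 1e4, 3)
  expect_lt(max(abs(correlation_matrix(big)[upper.tri(diag(3))])), 0.05)
  ts3 <- cbind(x = ts[, 1], flat = rep(1, 200))
  expect_error(correlation_matrix(ts3), "flat")
})

test_that("F + I shifts the spectrum by exactly one and repairs rank deficiency", {
  ones <- matrix(1, 3, 3)
  reg <- regularize_connectivity(ones)
  expect_equal(sort(eigen(reg, symmetric = TRUE)$values), c(1, 1, 4))
  expect_true(is_spd(reg))
  expect_equal(regularize_connectivity(diag(4)), 2 * diag(4), ignore_attr = TRUE)
  set.seed(3)
  S <- make_sym(5)
  shift <- eigen(regularize_connectivity(S), symmetric = TRUE, only.values = TRUE)$values -
    eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(shift, rep(1, 5), tolerance = 1e-12)
})

test_that("dataset regularisation is uniform by default, per-matrix on request", {
  good <- make_spd(3, seed = 4)
  bad <- matrix(1, 3, 3)          # rank 1, not SPD
  res_u <- regularize_dataset(list(good, bad))
  expect_true(all(res_u$regularised))
  expect_true(all(vapply(res_u$X, is_spd, logical(1))))
  res_p <- regularize_dataset(list(good, bad), mode = "per-matrix")
  expect_identical(res_p$regularised, c(FALSE, TRUE))
  expect_identical(res_p$X[[1]], good)
  res_ok <- regularize_dataset(list(good, make_spd(3, seed = 5)))
  expect_identical(res_ok$n_failed, 0L)
})

test_that("Fisher transform acts on the strict upper triangle entrywise", {
  F0 <- diag(3)
  expect_equal(fisher_transform_upper(F0), rep(0, 3))
  F1 <- diag(3)
  F1[1, 2] <- F1[2, 1] <- 0.5
  v <- fisher_transform_upper(F1)
  expect_length(v, 3)
  expect_equal(v[1], atanh(0.5))
  expect_equal(fisher_transform_upper(-F1 + 2 * diag(3))[1], -atanh(0.5))
  F2 <- F1; F2[1, 3] <- F2[3, 1] <- 1
  expect_error(fisher_transform_upper(F2), "infinite")
})

test_that("coefficient columns fold back to symmetric matrices exactly", {
  set.seed(6)
  R <- 5
  S <- make_sym(R)
  v <- vectorize_sym(S)
  expect_equal(coefficient_to_matrix(v, R), S, tolerance = 1e-14)
  expect_identical(coefficient_to_matrix(rep(0, 15), R), matrix(0, R, R))
  # each coordinate maps back to its (row, col) cell divided by the scale
  idx <- sym_vec_index(R)
  j <- which(!idx$diagonal)[4]
  e <- replace(rep(0, 15), j, 1)
  M <- coefficient_to_matrix(e, R)
  expect_equal(M[idx$row[j], idx$col[j]], 1 / sqrt(2))
  expect_error(coefficient_to_matrix(rep(0, 14), R), "length")
})

test_that("network averages match a brute-force pair enumeration", {
  coef <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  vals <- c(ab = 1, ac = 2, ad = 3, bc = 4, bd = 5, cd = 6)
  coef["a", "b"] <- coef["b", "a"] <- vals["ab"]
  coef["a", "c"] <- coef["c", "a"] <- vals["ac"]
  coef["a", "d"] <- coef["d", "a"] <- vals["ad"]
  coef["b", "c"] <- coef["c", "b"] <- vals["bc"]
  coef["b", "d"] <- coef["d", "b"] <- vals["bd"]
  coef["c", "d"] <- coef["d", "c"] <- vals["cd"]
  mapping <- data.frame(roi_label = letters[1:4], network = c("N1", "N1", "N2", "N2"))
  ns <- network_average(coef, mapping)
  expect_equal(ns$mean_coef["N1", "N1"], 1)                    # pair ab
  expect_equal(ns$mean_coef["N2", "N2"], 6)                    # pair cd
  expect_equal(ns$mean_coef["N1", "N2"], mean(c(2, 3, 4, 5)))  # spanning pairs
  expect_equal(ns$mean_coef["N2", "N1"], ns$mean_coef["N1", "N2"])
  # top quartile: ceiling(0.25 * 3) = 1 cell, the |6| within-N2 cell
  expect_identical(sum(ns$top_mask[upper.tri(ns$top_mask, diag = TRUE)]), 1L)
  expect_true(ns$top_mask["N2", "N2"])
})

test_that("single-ROI networks have undefined within-network cells; unmapped ROIs error", {
  coef <- matrix(0.5, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(coef) <- 0
  mapping <- data.frame(roi_label = c("a", "b", "c"), network = c("N1", "N1", "solo"))
  ns <- network_average(coef, mapping)
  expect_true(is.na(ns$mean_coef["solo", "solo"]))
  expect_equal(ns$mean_coef["N1", "solo"], 0.5)
  expect_error(network_average(coef, mapping[1:2, ]), "not mapped")
  # constant coefficients give every defined cell the constant
  expect_true(all(ns$mean_coef[!is.na(ns$mean_coef)] %in% c(0, 0.5)))
})

test_that("network summaries are equivariant under consistent ROI relabelling", {
  set.seed(7)
  R <- 6
  coef <- make_sym(R)
  labels <- paste0("roi", 1:R)
  dimnames(coef) <- list(labels, labels)
  mapping <- data.frame(roi_label = labels, network = rep(c("A", "B", "C"), each = 2))
  ns1 <- network_average(coef, mapping)
  perm <- sample(R)
  coef2 <- coef[perm, perm]
  mapping2 <- mapping[perm, ]
  ns2 <- network_average(coef2, mapping2)
  # same cells up to network ordering
  common <- intersect(ns1$networks, ns2$networks)
  expect_equal(ns2$mean_coef[common, common], ns1$mean_coef[common, common])
})
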