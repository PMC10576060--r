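# Variable importance in the projection (VIP), per-predictor permutation
# inference, and FDR control.

#' Redundancy of a response block with a score vector
#'
#' `Rd(Y, t) = mean over response columns of cor(Y_j, t)^2`: the average
#' proportion of variance in the responses explained by the score `t`.
#'
#' @param Y An `n x q` response matrix (or vector).
#' @param t A length-`n` score vector with nonzero variance.
#' @return A scalar in `[0, 1]`.
#' @export
redundancy <- function(Y, t) {
  Y <- as.matrix(Y)
  t <- as.numeric(t)
  if (nrow(Y) != length(t)) stop("`Y` and `t` must have matching length", call. = FALSE)
  if (stats::sd(t) == 0) stop("score `t` has zero variance", call. = FALSE)
  sds <- apply(Y, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("response column %d has zero variance", which(sds == 0)[1]), call. = FALSE)
  }
  mean(stats::cor(Y, t)^2)
}

#' VIP statistic of a fitted PLS model
#'
#' For predictor `j`,
#' `VIP_j = sqrt( p / Rd(Y, T) * sum_k Rd(Y, t_k) w_jk^2 )`,
#' where `Rd(Y, T) = sum_k Rd(Y, t_k)`.  Because NIPALS weights have unit
#' norm, `sum_j VIP_j^2 = p` identically, so VIP measures each predictor's
#' share of the explained response variance relative to an even split.
#'
#' @param fit A `pls_fit`.
#' @param Y The training response matrix the model was fitted to.
#' @return A nonnegative vector of length `p`.
#' @export
vip <- function(fit, Y) {
  stopifnot(inherits(fit, "pls_fit"))
  Y <- as.matrix(Y)
  Tm <- fit$x_scores
  rd <- vapply(seq_len(fit$K), function(k) redundancy(Y, Tm[, k]), numeric(1))
  rd_total <- sum(rd)
  if (rd_total <= 0) stop("model explains no response variance (Rd(Y, T) = 0)", call. = FALSE)
  drop(sqrt(fit$p / rd_total * (fit$weights^2 %*% rd)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped to 1.
#'
#' @param p A vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, componentwise `>=` the input.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("`p` must be numeric values in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Permutation test of the VIP statistic
#'
#' For each predictor `j`, the rows of tangent-coordinate column `j` are
#' permuted `H` times; each permutation refits the PLS model (same `K` as
#' the observed fit) and records the permuted VIP.  The raw p-value is the
#' fraction of permuted VIPs strictly exceeding the observed one, so raw
#' p-values lie on the grid `{0, 1/H, ..., 1}`; set `add_one = TRUE` for the
#' `(count + 1) / (H + 1)` variant that never returns exactly zero.
#' Predictors listed in `diagonal_idx` (tangent coordinates derived from
#' diagonal entries of a connectivity matrix, uninformative a priori) are
#' assigned p-value 1 without permutation.  P-values are then FDR-adjusted
#' and thresholded at `alpha`.
#'
#' A permutation whose refit fails (degenerate deflation) is redrawn and
#' counted in `n_redrawn`.  `shared_permutations = TRUE` draws one set of
#' `H` permutations and reuses it across predictors (an approximation that
#' cuts RNG cost; off by default).
#'
#' @param Xtan `n x p` tangent-coordinate (predictor) matrix.
#' @param Y `n x q` response matrix.
#' @param K Number of latent components (reused for every refit).
#' @param H Number of permutations (default 200).
#' @param alpha Significance level for the FDR-adjusted values (default 0.05).
#' @param seed Optional integer seed for the permutation stream.
#' @param diagonal_idx Integer indices of predictors masked to p-value 1.
#' @param add_one Use the positively-biased `(count + 1)/(H + 1)` estimate.
#' @param shared_permutations Reuse one permutation set across predictors.
#' @return An object of class `vip_result` with fields `vip`, `p_values`,
#'   `p_adjusted`, `significant`, `H`, `alpha`, `seed`, `diagonal_idx`,
#'   `n_redrawn`.
#' @export
vip_permutation_test <- function(Xtan, Y, K, H = 200L, alpha = 0.05, seed = NULL,
                                 diagonal_idx = integer(0), add_one = FALSE,
                                 shared_permutations = FALSE) {
  Xtan <- as.matrix(Xtan)
  Y <- as.matrix(Y)
  n <- nrow(Xtan)
  p <- ncol(Xtan)
  if (H < 1) stop("`H` must be at least 1", call. = FALSE)
  if (length(diagonal_idx) && (any(diagonal_idx < 1) || any(diagonal_idx > p))) {
    stop("`diagonal_idx` out of range", call. = FALSE)
  }

  fit0 <- nipals_fit(Xtan, Y, K)
  vip0 <- vip(fit0, Y)

  if (!is.null(seed)) set.seed(seed)
  perm_set <- if (shared_permutations) replicate(H, sample.int(n), simplify = FALSE)

  p_raw <- rep(1, p)
  n_redrawn <- 0L
  test_idx <- setdiff(seq_len(p), diagonal_idx)
  for (j in test_idx) {
    exceed <- 0L
    for (h in seq_len(H)) {
      first_try <- TRUE
      repeat {
        # A failed shared permutation is replaced by a fresh draw.
        perm <- if (shared_permutations && first_try) perm_set[[h]] else sample.int(n)
        first_try <- FALSE
        Xp <- Xtan
        Xp[, j] <- Xtan[perm, j]
        vj <- tryCatch({
          fit_h <- nipals_fit(Xp, Y, K)
          if (fit_h$truncated && !fit0$truncated) stop("truncated refit")
          vip(fit_h, Y)[j]
        }, error = function(e) NULL)
        if (!is.null(vj)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * H) stop("too many failed permutation refits", call. = FALSE)
      }
      if (vj > vip0[j]) exceed <- exceed + 1L
    }
    p_raw[j] <- if (add_one) (exceed + 1) / (H + 1) else exceed / H
  }

  p_adj <- fdr_adjust(p_raw)
  structure(
    list(
      vip = vip0,
      p_values = p_raw,
      p_adjusted = p_adj,
      significant = p_adj <= alpha,
      H = as.integer(H),
      alpha = alpha,
      seed = seed,
      diagonal_idx = as.integer(diagonal_idx),
      n_redrawn = n_redrawn,
      K = fit0$K
    ),
    class = "vip_result"
  )
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf(
    "VIP permutation test: %d predictors, H = %d, alpha = %g\n  %d significant after FDR (%d diagonal-masked)\n",
    length(x$vip), x$H, x$alpha, sum(x$significant), length(x$diagonal_idx)
  ))
  invisible(x)
}
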