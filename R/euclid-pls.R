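# Classical two-block partial least squares fitted by NIPALS, with the
# regression-coefficient formula beta = W (P'W)^{-1} B C' and prediction.

#' Fit a PLS model by NIPALS
#'
#' Extracts `K` latent components from column-centred `X` and `Y` by the
#' iterative NIPALS sequence: starting from a response column `u`, iterate
#' `w = X'u / |X'u|`, `t = X w`, `c = Y't / |Y't|`, `u = Y c` until the score
#' `t` stabilises (for a univariate response the loop closes in one pass).
#' After each component, `X` is deflated by `t p'` with `p = X't / t't` and,
#' by default, `Y` by `b t c'` with the inner-relation slope `b = u't / t't`.
#' With the unit-norm response weight, `b t c'` is exactly the projection of
#' the current `Y` on `t`, so at `K = rank(X)` the fitted values coincide
#' with the least-squares projection.
#'
#' Each weight vector has unit Euclidean norm and is sign-fixed so that its
#' largest-magnitude entry is positive, making the output deterministic.
#' Columns are centred internally but never scaled; standardise responses
#' upstream if required.
#'
#' If the deflated `X` (or `Y`) becomes numerically zero before `K`
#' components are extracted, the fit is truncated at the last extractable
#' component and flagged via `truncated = TRUE` rather than raising an error.
#'
#' @param X Numeric predictor matrix, `n x p`.
#' @param Y Numeric response matrix (or vector), `n x q`.
#' @param K Number of latent components; must satisfy `K <= min(p, n - 1)`.
#' @param deflate_y Deflate the response block after each component (the
#'   multi-response convention consistent with the diagonal inner relation).
#' @param inner_tol Relative convergence tolerance of the inner loop.
#' @param max_inner Maximum inner-loop iterations per component.
#' @return An object of class `pls_fit` with weights `W` (`p x K`), response
#'   weights `C`, loadings `P` and `Q`, scores `T` and `U`, inner-relation
#'   slopes `B`, regression coefficients, column means, the extracted `K`,
#'   the `requested_K`, and the `truncated` flag.
#' @export
nipals_fit <- function(X, Y, K, deflate_y = TRUE, inner_tol = 1e-10, max_inner = 500L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  q <- ncol(Y)
  if (nrow(Y) != n) stop("`X` and `Y` must have the same number of rows", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("`X` and `Y` must be finite", call. = FALSE)
  }
  kmax <- min(p, n - 1L)
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K > kmax) {
    stop(sprintf("`K` must be an integer in [1, min(p, n - 1)] = [1, %d]", kmax), call. = FALSE)
  }
  K <- as.integer(K)

  x_means <- colMeans(X)
  y_means <- colMeans(Y)
  Xc <- sweep(X, 2, x_means)
  Yc <- sweep(Y, 2, y_means)
  x_scale0 <- max(abs(Xc))
  y_scale0 <- max(abs(Yc))
  if (x_scale0 == 0) stop("`X` has zero variance in every column", call. = FALSE)
  if (y_scale0 == 0) stop("`Y` has zero variance in every column", call. = FALSE)

  W <- matrix(0, p, K)
  C <- matrix(0, q, K)
  P <- matrix(0, p, K)
  Q <- matrix(0, q, K)
  Tm <- matrix(0, n, K)
  U <- matrix(0, n, K)
  B <- numeric(K)
  k_eff <- 0L

  for (k in seq_len(K)) {
    if (max(abs(Xc)) <= 1e-12 * x_scale0 || max(abs(Yc)) <= 1e-12 * y_scale0) break
    u <- Yc[, 1]
    if (sum(u * u) == 0) u <- Yc[, which.max(colSums(Yc^2))]
    t_old <- NULL
    w <- NULL
    tvec <- NULL
    degenerate <- FALSE
    for (it in seq_len(max_inner)) {
      w <- drop(crossprod(Xc, u))
      wn <- sqrt(sum(w * w))
      if (wn == 0) {
        degenerate <- TRUE
        break
      }
      w <- w / wn
      tvec <- drop(Xc %*% w)
      if (q == 1L) break
      cvec <- drop(crossprod(Yc, tvec))
      cvec <- cvec / sqrt(sum(cvec * cvec))
      u <- drop(Yc %*% cvec)
      if (!is.null(t_old) &&
          sqrt(sum((tvec - t_old)^2)) <= inner_tol * sqrt(sum(tvec * tvec))) break
      t_old <- tvec
    }
    if (degenerate || sum(tvec * tvec) == 0) break

    # Deterministic sign: largest-magnitude weight entry positive.
    s <- sign(w[which.max(abs(w))])
    if (s == 0) s <- 1
    w <- s * w
    tvec <- s * tvec
    tt <- sum(tvec * tvec)
    cvec <- drop(crossprod(Yc, tvec))
    cn <- sqrt(sum(cvec * cvec))
    if (cn == 0) break
    cvec <- cvec / cn
    u <- drop(Yc %*% cvec)
    pvec <- drop(crossprod(Xc, tvec)) / tt
    b <- sum(u * tvec) / tt
    uu <- sum(u * u)
    qvec <- if (uu > 0) drop(crossprod(Yc, u)) / uu else rep(0, q)

    W[, k] <- w
    C[, k] <- cvec
    P[, k] <- pvec
    Q[, k] <- qvec
    Tm[, k] <- tvec
    U[, k] <- u
    B[k] <- b
    k_eff <- k

    Xc <- Xc - tcrossprod(tvec, pvec)
    if (deflate_y) Yc <- Yc - b * tcrossprod(tvec, cvec)
  }

  if (k_eff == 0L) {
    stop("no PLS component could be extracted (degenerate data)", call. = FALSE)
  }
  truncated <- k_eff < K
  keep <- seq_len(k_eff)
  fit <- structure(
    list(
      K = k_eff,
      requested_K = K,
      weights = W[, keep, drop = FALSE],
      y_weights = C[, keep, drop = FALSE],
      x_loadings = P[, keep, drop = FALSE],
      y_loadings = Q[, keep, drop = FALSE],
      x_scores = Tm[, keep, drop = FALSE],
      y_scores = U[, keep, drop = FALSE],
      inner_coeffs = B[keep],
      x_means = x_means,
      y_means = y_means,
      deflate_y = deflate_y,
      truncated = truncated,
      n = n, p = p, q = q
    ),
    class = "pls_fit"
  )
  fit$coefficients <- pls_coefficients(fit)
  fit
}

#' PLS regression coefficients
#'
#' Assembles the `p x q` coefficient matrix
#' `beta = W (P'W)^{-1} diag(B) C'` from the first `k` components of a fitted
#' model, so that centred predictors times `beta` reproduce the fitted
#' response.  A warning is issued when `P'W` has condition number above
#' `1e8`; a numerically singular `P'W` is an error naming the component at
#' which it occurs.
#'
#' @param fit A `pls_fit` object.
#' @param k Number of components to use (default: all extracted).
#' @return A `p x q` matrix.
#' @export
pls_coefficients <- function(fit, k = fit$K) {
  stopifnot(inherits(fit, "pls_fit"))
  if (k < 1 || k > fit$K) stop(sprintf("`k` must be in [1, %d]", fit$K), call. = FALSE)
  idx <- seq_len(k)
  M <- crossprod(fit$x_loadings[, idx, drop = FALSE], fit$weights[, idx, drop = FALSE])
  kap <- kappa(M, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12) {
    stop(sprintf("P'W is numerically singular at component %d", k), call. = FALSE)
  }
  if (kap > 1e8) {
    warning(sprintf("P'W is ill-conditioned (condition number %.2e) at %d components", kap, k))
  }
  rhs <- fit$inner_coeffs[idx] * t(fit$y_weights[, idx, drop = FALSE])
  fit$weights[, idx, drop = FALSE] %*% solve(M, rhs)
}

#' Predict from a fitted PLS model
#'
#' Returns `(Xnew - x_means) beta_k + y_means` using the coefficients from
#' the first `k` components.
#'
#' @param fit A `pls_fit` object.
#' @param Xnew Numeric matrix with the training number of columns.
#' @param k Number of components (default: all extracted).
#' @return An `m x q` matrix of predictions.
#' @export
pls_predict <- function(fit, Xnew, k = fit$K) {
  stopifnot(inherits(fit, "pls_fit"))
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != fit$p) {
    stop(sprintf("`Xnew` has %d columns; the model was trained with %d", ncol(Xnew), fit$p),
         call. = FALSE)
  }
  beta <- if (k == fit$K) fit$coefficients else pls_coefficients(fit, k)
  Xc <- sweep(Xnew, 2, fit$x_means)
  sweep(Xc %*% beta, 2, fit$y_means, `+`)
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("PLS fit (NIPALS): n = %d, p = %d, q = %d, K = %d%s\n",
              x$n, x$p, x$q, x$K,
              if (x$truncated) sprintf(" (truncated from %d)", x$requested_K) else ""))
  invisible(x)
}
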