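# Affine-invariant geometry on the manifold of symmetric positive definite
# (SPD) matrices: metric, geodesic distance, Exp/Log maps, and the Frechet
# mean by gradient descent.  All matrix functions go through the symmetric
# eigendecomposition with re-symmetrisation of the result.

# Relative tolerance below which a matrix is rejected as asymmetric, and the
# relative eigenvalue floor below which it is treated as rank-deficient.
.sym_tol <- 1e-10
.eps_pd <- 1e-10

symmetrize <- function(A) (A + t(A)) / 2

#' Test whether a matrix is symmetric positive definite
#'
#' A matrix passes when it is square, symmetric to relative tolerance
#' `1e-10`, and its smallest eigenvalue exceeds `1e-10` times its largest
#' (a scale-free positive-definiteness criterion).
#'
#' @param A A numeric matrix.
#' @return `TRUE` or `FALSE`.
#' @export
is_spd <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A) || !is.numeric(A)) return(FALSE)
  if (!all(is.finite(A))) return(FALSE)
  scale <- max(1, max(abs(A)))
  if (max(abs(A - t(A))) > .sym_tol * scale) return(FALSE)
  ev <- eigen(symmetrize(A), symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] > .eps_pd * max(ev[1], 0)
}

# Validate and symmetrise an SPD input; `what` names the argument in errors.
as_spd <- function(A, what = "A") {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop(sprintf("`%s` must be a square numeric matrix", what), call. = FALSE)
  }
  if (!all(is.finite(A))) {
    stop(sprintf("`%s` contains non-finite values", what), call. = FALSE)
  }
  scale <- max(1, max(abs(A)))
  if (max(abs(A - t(A))) > .sym_tol * scale) {
    stop(sprintf("`%s` is not symmetric to tolerance", what), call. = FALSE)
  }
  A <- symmetrize(A)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (!(ev[length(ev)] > .eps_pd * max(ev[1], 0))) {
    stop(sprintf(
      "`%s` is not positive definite (smallest eigenvalue %.3e vs largest %.3e)",
      what, ev[length(ev)], ev[1]
    ), call. = FALSE)
  }
  A
}

# Validate a symmetric (tangent) matrix.
as_sym <- function(U, what = "U") {
  if (!is.matrix(U) || nrow(U) != ncol(U)) {
    stop(sprintf("`%s` must be a square numeric matrix", what), call. = FALSE)
  }
  if (!all(is.finite(U))) {
    stop(sprintf("`%s` contains non-finite values", what), call. = FALSE)
  }
  scale <- max(1, max(abs(U)))
  if (max(abs(U - t(U))) > .sym_tol * scale) {
    stop(sprintf("`%s` is not symmetric to tolerance", what), call. = FALSE)
  }
  symmetrize(U)
}

# Apply a scalar function to the eigenvalues of a symmetric matrix.
sym_matfun <- function(A, f) {
  e <- eigen(A, symmetric = TRUE)
  symmetrize(e$vectors %*% (f(e$values) * t(e$vectors)))
}

#' Matrix power of an SPD matrix
#'
#' Computes `A^alpha` through the symmetric eigendecomposition: the result has
#' the same eigenvectors as `A` and eigenvalues raised to `alpha`.  Used for
#' the square roots `A^{1/2}`, `A^{-1/2}` appearing throughout the
#' affine-invariant geometry.
#'
#' @param A An SPD matrix.
#' @param alpha A real exponent.
#' @return A symmetric matrix; SPD whenever `A` is SPD.
#' @export
spd_power <- function(A, alpha) {
  A <- as_spd(A)
  sym_matfun(A, function(l) l^alpha)
}

# Matrix exponential / logarithm of symmetric matrices (spectral).
sym_exp <- function(U) sym_matfun(U, exp)
spd_logm <- function(A) sym_matfun(A, log)

#' Affine-invariant Riemannian metric
#'
#' The inner product of two tangent vectors `U`, `V` at the base point `A`:
#' `g_A(U, V) = Tr(U A^-1 V A^-1)`.  It is symmetric, bilinear, positive
#' definite, and invariant under the congruence `A -> G A G^T`,
#' `U -> G U G^T` for any invertible `G`.
#'
#' @param A An SPD base point.
#' @param U,V Symmetric matrices (tangent vectors at `A`).
#' @return A scalar.
#' @export
affine_metric <- function(A, U, V) {
  A <- as_spd(A)
  U <- as_sym(U, "U")
  V <- as_sym(V, "V")
  if (!all(dim(U) == dim(A)) || !all(dim(V) == dim(A))) {
    stop("`U` and `V` must match the dimension of `A`", call. = FALSE)
  }
  Ai <- spd_power(A, -1)
  # Tr(U Ai V Ai) = sum((U Ai) * t(V Ai))
  sum((U %*% Ai) * t(V %*% Ai))
}

#' Geodesic distance between SPD matrices
#'
#' Under the affine-invariant geometry,
#' `d(A, B)^2 = sum_r log(sigma_r)^2` where `sigma_r` are the eigenvalues of
#' the whitened matrix `A^{-1/2} B A^{-1/2}`.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return A nonnegative scalar.
#' @export
geodesic_distance <- function(A, B) {
  A <- as_spd(A, "A")
  B <- as_spd(B, "B")
  if (!all(dim(A) == dim(B))) stop("`A` and `B` must have equal dimension", call. = FALSE)
  Aih <- sym_matfun(A, function(l) l^(-0.5))
  M <- symmetrize(Aih %*% B %*% Aih)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(ev)^2))
}

#' Riemannian exponential map on SPD matrices
#'
#' `Exp_A(U) = A^{1/2} expm(A^{-1/2} U A^{-1/2}) A^{1/2}`, mapping a tangent
#' vector at `A` to a point on the manifold.  `exp_map(A, 0) = A`.
#'
#' @param A An SPD base point.
#' @param U A symmetric matrix (tangent vector at `A`).
#' @return An SPD matrix.
#' @export
exp_map <- function(A, U) {
  A <- as_spd(A)
  U <- as_sym(U, "U")
  if (!all(dim(U) == dim(A))) stop("`U` must match the dimension of `A`", call. = FALSE)
  e <- eigen(A, symmetric = TRUE)
  Ah <- symmetrize(e$vectors %*% (sqrt(e$values) * t(e$vectors)))
  Aih <- symmetrize(e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors)))
  symmetrize(Ah %*% sym_exp(symmetrize(Aih %*% U %*% Aih)) %*% Ah)
}

#' Riemannian logarithm map on SPD matrices
#'
#' `Log_A(B) = A^{1/2} logm(A^{-1/2} B A^{-1/2}) A^{1/2}`, the inverse of
#' [exp_map()]: the tangent vector at `A` pointing along the geodesic to `B`,
#' whose metric norm equals `geodesic_distance(A, B)`.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return A symmetric matrix (tangent vector at `A`).
#' @export
log_map <- function(A, B) {
  A <- as_spd(A, "A")
  B <- as_spd(B, "B")
  if (!all(dim(A) == dim(B))) stop("`A` and `B` must have equal dimension", call. = FALSE)
  e <- eigen(A, symmetric = TRUE)
  Ah <- symmetrize(e$vectors %*% (sqrt(e$values) * t(e$vectors)))
  Aih <- symmetrize(e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors)))
  symmetrize(Ah %*% spd_logm(symmetrize(Aih %*% B %*% Aih)) %*% Ah)
}

#' Frechet mean of SPD matrices
#'
#' The Frechet (intrinsic) mean minimises the sum of squared geodesic
#' distances to the sample.  It is computed by gradient descent: from the
#' current estimate `mu`, move along `Exp_mu(step/n * sum_i Log_mu(X_i))`
#' until the Frobenius norm of the mean tangent vector falls below `tol`.
#' Initialisation is the arithmetic mean of the inputs with eigenvalues
#' floored to keep it positive definite.
#'
#' @param points A list of SPD matrices of equal dimension.
#' @param step Gradient-descent step size (default 1).
#' @param tol Convergence tolerance on the Frobenius norm of the mean tangent
#'   vector (default `1e-8`).
#' @param max_iter Maximum number of iterations (default 100).
#' @return An object of class `frechet_mean` with elements `mean`,
#'   `iterations`, `final_gradient_norm`, `converged`, and the per-iteration
#'   `objective` (sum of squared distances), which is non-increasing.
#' @export
frechet_mean <- function(points, step = 1, tol = 1e-8, max_iter = 100L) {
  if (!is.list(points) || length(points) == 0) {
    stop("`points` must be a nonempty list of SPD matrices", call. = FALSE)
  }
  points <- lapply(seq_along(points), function(i) as_spd(points[[i]], sprintf("points[[%d]]", i)))
  R <- nrow(points[[1]])
  if (!all(vapply(points, nrow, 1L) == R)) {
    stop("all matrices in `points` must have equal dimension", call. = FALSE)
  }
  n <- length(points)
  if (n == 1L) {
    return(structure(
      list(mean = points[[1]], iterations = 0L, final_gradient_norm = 0,
           converged = TRUE, objective = numeric(0)),
      class = "frechet_mean"
    ))
  }

  # Arithmetic-mean initialisation, eigenvalues floored to stay SPD.
  init <- symmetrize(Reduce(`+`, points) / n)
  e <- eigen(init, symmetric = TRUE)
  floor_val <- max(e$values[1], 1) * 1e-8
  mu <- symmetrize(e$vectors %*% (pmax(e$values, floor_val) * t(e$vectors)))

  objective <- numeric(0)
  gnorm <- Inf
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- eigen(mu, symmetric = TRUE)
    Ah <- symmetrize(e$vectors %*% (sqrt(e$values) * t(e$vectors)))
    Aih <- symmetrize(e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors)))
    # Tangents in the whitened frame: log(mu^{-1/2} X mu^{-1/2}).  The
    # geodesic distance to X is the Frobenius norm of that matrix log, so the
    # objective trace is free.
    Wbar <- matrix(0, R, R)
    obj <- 0
    for (X in points) {
      Wi <- spd_logm(symmetrize(Aih %*% X %*% Aih))
      Wbar <- Wbar + Wi
      obj <- obj + sum(Wi * Wi)
    }
    Wbar <- Wbar / n
    objective <- c(objective, obj)
    # Mean tangent in the original frame is Ah %*% Wbar %*% Ah.
    grad <- symmetrize(Ah %*% Wbar %*% Ah)
    gnorm <- sqrt(sum(grad * grad))
    iterations <- it
    if (gnorm <= tol) {
      converged <- TRUE
      break
    }
    mu <- symmetrize(Ah %*% sym_exp(step * Wbar) %*% Ah)
  }

  structure(
    list(mean = mu, iterations = iterations, final_gradient_norm = gnorm,
         converged = converged, objective = objective),
    class = "frechet_mean"
  )
}

#' @export
print.frechet_mean <- function(x, ...) {
  cat(sprintf(
    "Frechet mean of %dx%d SPD matrices: %s after %d iteration(s), |grad| = %.3e\n",
    nrow(x$mean), ncol(x$mean),
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$final_gradient_norm
  ))
  invisible(x)
}
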