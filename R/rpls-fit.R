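# Riemannian PLS via tangent-space NIPALS (tNIPALS): linearise manifold data
# at the Frechet mean with the Riemannian logarithm, vectorise, and run
# Euclidean NIPALS on the tangent coordinates.

#' Manifold specification
#'
#' Declares which geometry a data block lives on.  `"euclidean"` uses vector
#' addition/subtraction for Exp/Log and the arithmetic mean;
#' `"spd_affine_invariant"` uses the affine-invariant geometry of symmetric
#' positive definite matrices.
#'
#' @param kind One of `"euclidean"`, `"spd_affine_invariant"`.
#' @param dim For the SPD manifold, the matrix dimension `R`; for the
#'   Euclidean manifold, the vector dimension.
#' @return An object of class `rpls_manifold`.
#' @export
manifold <- function(kind = c("euclidean", "spd_affine_invariant"), dim) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(dim), length(dim) == 1L, dim >= 1)
  structure(list(kind = kind, dim = as.integer(dim)), class = "rpls_manifold")
}

# Index map for the row-major upper triangle (including the diagonal):
# (1,1),(1,2),...,(1,R),(2,2),...  Returned as a tibble with the flat index,
# (row, col) position, and a diagonal flag.
#' Tangent-coordinate index map
#'
#' Maps flat tangent-coordinate indices (the columns NIPALS sees) back to
#' `(row, col)` positions of the symmetric matrix under the row-major
#' upper-triangle ordering used by [vectorize_sym()].
#'
#' @param R Matrix dimension.
#' @param roi_labels Optional length-`R` character vector of ROI names; when
#'   supplied a `label` column (`"roi_i--roi_j"`) is added.
#' @return A tibble with columns `idx`, `row`, `col`, `diagonal` (and
#'   optionally `label`).
#' @export
sym_vec_index <- function(R, roi_labels = NULL) {
  rows <- unlist(lapply(seq_len(R), function(i) rep(i, R - i + 1L)))
  cols <- unlist(lapply(seq_len(R), function(i) i:R))
  out <- tibble::tibble(
    idx = seq_along(rows),
    row = rows,
    col = cols,
    diagonal = rows == cols
  )
  if (!is.null(roi_labels)) {
    stopifnot(length(roi_labels) == R)
    out$label <- paste(roi_labels[rows], roi_labels[cols], sep = "--")
  }
  out
}

#' Vectorise a symmetric matrix
#'
#' Flattens the upper triangle (diagonal included) row-major into a vector of
#' length `R(R+1)/2`, multiplying off-diagonal entries by `scale_offdiag`.
#' With the default `sqrt(2)` scaling the Euclidean dot product of two
#' vectorised matrices equals their Frobenius inner product `Tr(U V)`, so
#' NIPALS on vectorised tangents respects tangent-space geometry.
#'
#' @param S A symmetric matrix.
#' @param scale_offdiag Multiplier applied to off-diagonal entries
#'   (default `sqrt(2)`; use 1 for the unscaled half-vectorisation).
#' @return A numeric vector of length `R(R+1)/2`.
#' @export
vectorize_sym <- function(S, scale_offdiag = sqrt(2)) {
  S <- as_sym(S, "S")
  R <- nrow(S)
  # Column-major lower triangle of t(S) is the row-major upper triangle of S.
  v <- t(S)[lower.tri(S, diag = TRUE)]
  if (scale_offdiag != 1) {
    offdiag <- !sym_diag_mask(R)
    v[offdiag] <- v[offdiag] * scale_offdiag
  }
  v
}

# Logical mask over the flat index marking diagonal coordinates.
sym_diag_mask <- function(R) {
  unlist(lapply(seq_len(R), function(i) c(TRUE, rep(FALSE, R - i))))
}

#' Invert [vectorize_sym()]
#'
#' @param v A numeric vector of length `R(R+1)/2`.
#' @param R Matrix dimension.
#' @param scale_offdiag The off-diagonal scale used when vectorising.
#' @return The symmetric `R x R` matrix whose vectorisation is `v`.
#' @export
unvectorize_sym <- function(v, R, scale_offdiag = sqrt(2)) {
  d <- R * (R + 1L) / 2L
  if (length(v) != d) {
    stop(sprintf("`v` has length %d; expected R(R+1)/2 = %d for R = %d", length(v), d, R),
         call. = FALSE)
  }
  if (scale_offdiag != 1) {
    offdiag <- !sym_diag_mask(R)
    v[offdiag] <- v[offdiag] / scale_offdiag
  }
  S <- matrix(0, R, R)
  S[lower.tri(S, diag = TRUE)] <- v
  S <- t(S)
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

# Infer a manifold spec from a data block.
infer_manifold <- function(data, what) {
  if (is.list(data) && !is.data.frame(data)) {
    if (!length(data)) stop(sprintf("`%s` is an empty list", what), call. = FALSE)
    manifold("spd_affine_invariant", nrow(data[[1]]))
  } else {
    m <- as.matrix(data)
    manifold("euclidean", ncol(m))
  }
}

# Tangent-coordinate matrix for a list of SPD points at base mu.  With
# whiten = TRUE the tangent U is first mapped to mu^{-1/2} U mu^{-1/2}
# (which equals logm(mu^{-1/2} X mu^{-1/2}) directly), so that the Frobenius
# product of coordinates equals the affine-invariant metric at mu.
spd_tangent_coords <- function(points, mu, scale_offdiag = sqrt(2), whiten = FALSE) {
  e <- eigen(mu, symmetric = TRUE)
  Ah <- symmetrize(e$vectors %*% (sqrt(e$values) * t(e$vectors)))
  Aih <- symmetrize(e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors)))
  rows <- lapply(points, function(X) {
    Wi <- spd_logm(symmetrize(Aih %*% X %*% Aih))
    U <- if (whiten) Wi else symmetrize(Ah %*% Wi %*% Ah)
    vectorize_sym(U, scale_offdiag)
  })
  do.call(rbind, rows)
}

#' Fit Riemannian PLS by tangent-space NIPALS
#'
#' Computes the Frechet mean of each manifold-valued block, maps every
#' observation into the mean's tangent space with the Riemannian logarithm,
#' vectorises symmetric tangents (see [vectorize_sym()]), and fits Euclidean
#' NIPALS ([nipals_fit()]) on the resulting coordinates.  For a Euclidean
#' block the linearisation at the mean composed with NIPALS's internal
#' column-centring is exactly column-centring, so the raw matrix is passed
#' through and the model reduces exactly to standard PLS.
#'
#' @param X Predictors: a list of SPD matrices, or an `n x p` numeric matrix
#'   for Euclidean predictors.
#' @param Y Responses: an `n x q` numeric matrix/data frame (Euclidean), or a
#'   list of SPD matrices.
#' @param K Number of latent components.
#' @param x_manifold,y_manifold Optional [manifold()] specs; inferred from
#'   the data type when `NULL`.
#' @param scale_offdiag Off-diagonal scale for symmetric-tangent
#'   vectorisation (default `sqrt(2)`).
#' @param whiten When `TRUE`, SPD tangents are whitened at the mean
#'   (`U -> mu^{-1/2} U mu^{-1/2}`) before vectorisation, making the fit
#'   exactly equivariant under congruence transformations of the data.
#' @param frechet_control List of arguments (`step`, `tol`, `max_iter`)
#'   passed to [frechet_mean()].
#' @param deflate_y Passed to [nipals_fit()].
#' @return An object of class `rpls_fit`: manifold specs, Frechet means
#'   `mu_X`/`mu_Y`, the vectorisation convention, and the embedded `pls`
#'   fit on tangent coordinates.
#' @export
tnipals_fit <- function(X, Y, K, x_manifold = NULL, y_manifold = NULL,
                        scale_offdiag = sqrt(2), whiten = FALSE,
                        frechet_control = list(), deflate_y = TRUE) {
  x_manifold <- x_manifold %||% infer_manifold(X, "X")
  y_manifold <- y_manifold %||% infer_manifold(Y, "Y")

  lin <- function(data, man, what) {
    if (man$kind == "spd_affine_invariant") {
      stopifnot(is.list(data))
      data <- lapply(seq_along(data), function(i) as_spd(data[[i]], sprintf("%s[[%d]]", what, i)))
      fm <- do.call(frechet_mean, c(list(points = data), frechet_control))
      if (!fm$converged) {
        stop(sprintf(
          "Frechet mean of `%s` did not converge (|grad| = %.3e); reduce `step` in `frechet_control`",
          what, fm$final_gradient_norm
        ), call. = FALSE)
      }
      list(mu = fm$mean,
           coords = spd_tangent_coords(data, fm$mean, scale_offdiag, whiten))
    } else {
      m <- as.matrix(data)
      storage.mode(m) <- "double"
      # Euclidean Log at the mean is subtraction of a constant row, which
      # NIPALS's centring removes exactly; pass the raw coordinates through.
      list(mu = colMeans(m), coords = m)
    }
  }

  xl <- lin(X, x_manifold, "X")
  yl <- lin(Y, y_manifold, "Y")
  n <- nrow(xl$coords)
  if (nrow(yl$coords) != n) stop("`X` and `Y` must have the same number of observations", call. = FALSE)

  pls <- nipals_fit(xl$coords, yl$coords, K, deflate_y = deflate_y)

  structure(
    list(
      x_manifold = x_manifold,
      y_manifold = y_manifold,
      mu_X = xl$mu,
      mu_Y = yl$mu,
      vectorisation = list(order = "row-major-upper", scale_offdiag = scale_offdiag,
                           whiten = whiten),
      pls = pls,
      K = pls$K,
      n = n
    ),
    class = "rpls_fit"
  )
}

#' Predict from a Riemannian PLS fit
#'
#' New predictors are log-mapped at the *training* Frechet mean (never
#' recomputed), vectorised with the training convention, and pushed through
#' the tangent-space regression; a manifold-valued response is then mapped
#' back with the exponential at the training response mean.
#'
#' @param fit An `rpls_fit`.
#' @param Xnew New predictors in the same form as the training `X`.
#' @param k Number of components to use (default: all extracted).
#' @return For a Euclidean response, an `m x q` matrix; for an SPD response,
#'   a list of SPD matrices.
#' @export
rpls_predict <- function(fit, Xnew, k = fit$K) {
  stopifnot(inherits(fit, "rpls_fit"))
  sc <- fit$vectorisation$scale_offdiag
  wh <- fit$vectorisation$whiten
  coords <- if (fit$x_manifold$kind == "spd_affine_invariant") {
    stopifnot(is.list(Xnew))
    Xnew <- lapply(seq_along(Xnew), function(i) as_spd(Xnew[[i]], sprintf("Xnew[[%d]]", i)))
    if (nrow(Xnew[[1]]) != fit$x_manifold$dim) {
      stop("`Xnew` dimension does not match the training manifold", call. = FALSE)
    }
    spd_tangent_coords(Xnew, fit$mu_X, sc, wh)
  } else {
    m <- as.matrix(Xnew)
    if (ncol(m) != fit$x_manifold$dim) {
      stop("`Xnew` has the wrong number of columns", call. = FALSE)
    }
    m
  }
  pred <- pls_predict(fit$pls, coords, k)

  if (fit$y_manifold$kind == "spd_affine_invariant") {
    R <- fit$y_manifold$dim
    e <- eigen(fit$mu_Y, symmetric = TRUE)
    Ah <- symmetrize(e$vectors %*% (sqrt(e$values) * t(e$vectors)))
    lapply(seq_len(nrow(pred)), function(i) {
      U <- unvectorize_sym(pred[i, ], R, sc)
      if (wh) U <- symmetrize(Ah %*% U %*% Ah)
      exp_map(fit$mu_Y, U)
    })
  } else {
    pred
  }
}

#' @export
print.rpls_fit <- function(x, ...) {
  cat(sprintf(
    "Riemannian PLS fit (tNIPALS): n = %d, K = %d\n  X: %s (dim %d)\n  Y: %s (dim %d)\n",
    x$n, x$K, x$x_manifold$kind, x$x_manifold$dim,
    x$y_manifold$kind, x$y_manifold$dim
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
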