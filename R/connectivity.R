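# Functional-connectivity predictors: Pearson correlation matrices, the
# F + I regularisation for rank-deficient matrices, Fisher-transformed
# upper-triangle features, and network-level coefficient summaries.

#' Pearson correlation (functional connectivity) matrix
#'
#' @param timeseries A `T x R` matrix of ROI time series (rows = time points).
#' @param roi_labels Optional ROI names (default: column names).
#' @return A symmetric correlation matrix with unit diagonal; ROI labels are
#'   attached as dimnames and a `regularised = FALSE` attribute is set.
#' @export
correlation_matrix <- function(timeseries, roi_labels = colnames(timeseries)) {
  ts <- as.matrix(timeseries)
  if (nrow(ts) < 3) stop("at least 3 time points are required", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    lab <- if (!is.null(roi_labels)) roi_labels[bad] else as.character(bad)
    stop(sprintf("ROI `%s` has zero variance", lab), call. = FALSE)
  }
  C <- stats::cor(ts)
  C <- symmetrize(C)
  diag(C) <- 1
  if (!is.null(roi_labels)) dimnames(C) <- list(roi_labels, roi_labels)
  attr(C, "regularised") <- FALSE
  C
}

#' Regularise a connectivity matrix
#'
#' Adds the identity: `F + I` shifts every eigenvalue up by exactly 1, so any
#' positive semi-definite correlation matrix (including rank-deficient ones)
#' becomes strictly positive definite.  When one matrix in a dataset is
#' rank-deficient, apply this to *all* matrices of the dataset so that the
#' diagonal is consistent across subjects (see [regularize_dataset()]).
#'
#' @param F A symmetric connectivity matrix.
#' @return `F + I`, with the `regularised` attribute set to `TRUE`.
#' @export
regularize_connectivity <- function(F) {
  F <- as_sym(F, "F")
  out <- F + diag(nrow(F))
  attr(out, "regularised") <- TRUE
  out
}

#' Regularise a dataset of connectivity matrices when needed
#'
#' Checks every matrix against the SPD criterion.  In `"uniform"` mode
#' (default), if any matrix fails, *all* matrices receive the `F + I`
#' regularisation so every subject shares the same geometry; `"per-matrix"`
#' regularises only the failing matrices.
#'
#' @param X A list of symmetric connectivity matrices.
#' @param mode `"uniform"` or `"per-matrix"`.
#' @return A list with elements `X` (the possibly regularised matrices),
#'   `regularised` (logical per matrix), and `n_failed`.
#' @export
regularize_dataset <- function(X, mode = c("uniform", "per-matrix")) {
  mode <- match.arg(mode)
  failed <- !vapply(X, is_spd, logical(1))
  if (!any(failed)) {
    return(list(X = X, regularised = rep(FALSE, length(X)), n_failed = 0L))
  }
  if (mode == "uniform") {
    list(X = lapply(X, regularize_connectivity),
         regularised = rep(TRUE, length(X)), n_failed = sum(failed))
  } else {
    X[failed] <- lapply(X[failed], regularize_connectivity)
    list(X = X, regularised = failed, n_failed = sum(failed))
  }
}

# Strict upper triangle, row-major, consistent with vectorize_sym minus the
# diagonal entries.
upper_triangle_values <- function(F) {
  F <- as.matrix(F)
  t(F)[lower.tri(F)]
}

#' Fisher-transformed upper-triangle features
#'
#' `arctanh` applied to the strict upper triangle of a correlation matrix,
#' flattened row-major (the ordering of [vectorize_sym()] with the diagonal
#' removed).  These are the variance-stabilised Euclidean comparator
#' features; length `R(R-1)/2`.
#'
#' @param F A symmetric correlation matrix with off-diagonals strictly
#'   inside `(-1, 1)`.
#' @return A numeric vector of length `R(R-1)/2`.
#' @export
fisher_transform_upper <- function(F) {
  v <- upper_triangle_values(as_sym(F, "F"))
  if (any(abs(v) >= 1)) {
    stop("off-diagonal correlation with |r| >= 1: Fisher transform is infinite", call. = FALSE)
  }
  atanh(v)
}

#' Fold a coefficient column back into a symmetric matrix
#'
#' Inverts the tangent-coordinate vectorisation (undoing the off-diagonal
#' scaling) so a column of the PLS coefficient matrix can be read as a
#' symmetric ROI-by-ROI effect matrix.
#'
#' @param beta_column Coefficient vector of length `R(R+1)/2`.
#' @param R Matrix dimension.
#' @param scale_offdiag The off-diagonal scale used by the fit's
#'   vectorisation convention.
#' @return A symmetric `R x R` matrix.
#' @export
coefficient_to_matrix <- function(beta_column, R, scale_offdiag = sqrt(2)) {
  unvectorize_sym(as.numeric(beta_column), R, scale_offdiag)
}

#' Average coefficients within and between resting-state networks
#'
#' For each unordered pair of networks, averages the coefficient over all
#' distinct ROI pairs inside one network (within-network cell) or spanning
#' the two networks (between-network cell).  A network with a single ROI has
#' no within-network connections, so its diagonal cell is `NA`.  The
#' `top_mask` flags the top quartile of defined cells by absolute averaged
#' coefficient (`ceiling(0.25 * n_defined)` cells; ties broken by first
#' occurrence in row-major order).
#'
#' @param coef A symmetric `R x R` coefficient matrix.
#' @param roi_to_network A data frame with columns `roi_label`, `network`,
#'   or a named character vector mapping ROI label to network.  ROI order
#'   follows the dimnames of `coef` when present, else the mapping order.
#' @return An object of class `network_summary` with `networks`,
#'   `mean_coef` (symmetric network-by-network, `NA` where undefined) and
#'   `top_mask`.
#' @export
network_average <- function(coef, roi_to_network) {
  coef <- as_sym(coef, "coef")
  R <- nrow(coef)
  if (is.data.frame(roi_to_network)) {
    if (!all(c("roi_label", "network") %in% names(roi_to_network))) {
      stop("`roi_to_network` needs columns `roi_label` and `network`", call. = FALSE)
    }
    map <- stats::setNames(as.character(roi_to_network$network),
                           as.character(roi_to_network$roi_label))
  } else {
    map <- roi_to_network
  }
  roi_labels <- rownames(coef) %||% names(map)
  if (length(roi_labels) != R) {
    stop("cannot determine ROI labels: give `coef` dimnames or a complete mapping", call. = FALSE)
  }
  if (!all(roi_labels %in% names(map))) {
    missing <- setdiff(roi_labels, names(map))
    stop(sprintf("ROI `%s` is not mapped to a network", missing[1]), call. = FALSE)
  }
  net_of <- map[roi_labels]
  networks <- unique(unname(net_of))
  G <- length(networks)

  mean_coef <- matrix(NA_real_, G, G, dimnames = list(networks, networks))
  for (a in seq_len(G)) {
    for (b in a:G) {
      ia <- which(net_of == networks[a])
      ib <- which(net_of == networks[b])
      vals <- if (a == b) {
        if (length(ia) < 2) NULL else coef[ia, ia][upper.tri(diag(length(ia)))]
      } else {
        as.vector(coef[ia, ib, drop = FALSE])
      }
      if (!is.null(vals) && length(vals)) {
        mean_coef[a, b] <- mean(vals)
        mean_coef[b, a] <- mean_coef[a, b]
      }
    }
  }

  # Top quartile of defined cells by |mean|, row-major over the upper triangle.
  cells <- which(upper.tri(mean_coef, diag = TRUE) & !is.na(mean_coef), arr.ind = TRUE)
  cells <- cells[order(cells[, "row"], cells[, "col"]), , drop = FALSE]
  vals <- abs(mean_coef[cells])
  n_top <- ceiling(0.25 * length(vals))
  top_mask <- matrix(FALSE, G, G, dimnames = list(networks, networks))
  if (n_top > 0) {
    ord <- order(-vals) # stable: ties keep row-major order
    sel <- cells[ord[seq_len(n_top)], , drop = FALSE]
    top_mask[sel] <- TRUE
    top_mask[sel[, c(2, 1), drop = FALSE]] <- TRUE
  }

  structure(
    list(networks = networks, mean_coef = mean_coef, top_mask = top_mask,
         n_defined = length(vals), n_top = n_top),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Network summary: %d networks, %d defined cells, top quartile = %d cells\n",
              length(x$networks), x$n_defined, x$n_top))
  invisible(x)
}
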