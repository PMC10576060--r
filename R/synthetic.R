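# Seeded generators with known ground truth: SPD predictors drawn from the
# Riemannian PLS forward model, and group-structured ROI time series with a
# phenotype table.  All randomness flows from a single integer seed; the
# master seed initialises one stream from which sub-draws are taken in a
# fixed order, so regeneration is exact.

#' Random SPD matrix
#'
#' Random orthogonal eigenvectors (QR of a Gaussian matrix) with eigenvalues
#' drawn uniformly from `eig_range`.
#'
#' @param R Dimension.
#' @param eig_range Range of the eigenvalues (default `c(0.5, 2)`).
#' @return An SPD matrix.
#' @export
random_spd <- function(R, eig_range = c(0.5, 2)) {
  Qm <- qr.Q(qr(matrix(stats::rnorm(R * R), R, R)))
  symmetrize(Qm %*% (stats::runif(R, eig_range[1], eig_range[2]) * t(Qm)))
}

# Random symmetric matrix with iid N(0, sd^2) entries on the upper triangle
# (diagonal included), mirrored below.
random_sym <- function(R, sd = 1) {
  d <- R * (R + 1L) / 2L
  unvectorize_sym(stats::rnorm(d, 0, sd), R, scale_offdiag = 1)
}

#' Generate a dataset from the Riemannian PLS forward model
#'
#' Draws a base point `mu_X`, `L` tangent loadings orthonormal under the
#' vectorised (Frobenius) inner product, and centred Gaussian scores
#' `t_il ~ N(0, score_sd_l^2)`.  Each SPD predictor is
#' `X_i = Exp(Exp_mu(sum_l t_il p_l), e_i)` with symmetric Gaussian tangent
#' noise `e_i` of scale `noise_sd_x` injected at the noiseless point.  The
#' latent response scores follow the linear inner relation
#' `u_il = beta0_l + beta1_l t_il + noise`, and the Euclidean responses are
#' `Y_i = sum_l u_il q_l + f_i` with unit-norm response loadings `q_l`
#' (orthonormal when `L <= q`) and Gaussian noise `f_i`; `noise_sd_y` scales
#' both the inner-relation noise and `f_i`.
#'
#' @param n Number of subjects.
#' @param R Matrix dimension of the SPD predictors.
#' @param L Number of latent components planted.
#' @param q Number of Euclidean response variables (default 2).
#' @param score_sd Decreasing length-`L` vector of score standard deviations
#'   (default `0.4 * 0.75^(0:(L-1))`, keeping the data in a moderate
#'   neighbourhood of the mean where the tangent approximation is good).
#' @param noise_sd_x Tangent-noise scale for the predictors (default 0.05).
#' @param noise_sd_y Noise scale for the inner relation and the responses
#'   (default 0.05).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param beta0,beta1 Inner-relation intercepts/slopes (defaults 0 and 1).
#' @return An object of class `rpls_dataset`: `X` (list of SPD matrices),
#'   `Y` (`n x q` matrix), `true_mu_X`, `true_loadings` (list of `L`
#'   symmetric matrices), `true_scores`, `true_inner`, `q_loadings`, the
#'   noise scales and the seed.
#' @export
generate_rpls_dataset <- function(n, R, L, q = 2L,
                                  score_sd = NULL,
                                  noise_sd_x = 0.05, noise_sd_y = 0.05,
                                  seed = NULL,
                                  beta0 = rep(0, L), beta1 = rep(1, L)) {
  d <- R * (R + 1L) / 2L
  if (L < 1 || L > d) stop("`L` must be between 1 and R(R+1)/2", call. = FALSE)
  if (noise_sd_x < 0 || noise_sd_y < 0) stop("noise standard deviations must be >= 0", call. = FALSE)
  score_sd <- score_sd %||% (0.4 * 0.75^(seq_len(L) - 1))
  if (length(score_sd) != L || any(diff(score_sd) > 0)) {
    stop("`score_sd` must be a non-increasing vector of length L", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  mu_X <- random_spd(R)

  # Orthonormal tangent loadings: Gram-Schmidt on vectorised Gaussian
  # symmetric matrices under the Frobenius inner product.
  raw <- matrix(stats::rnorm(d * L), d, L)
  basis <- qr.Q(qr(raw))[, seq_len(L), drop = FALSE]
  loadings <- lapply(seq_len(L), function(l) unvectorize_sym(basis[, l], R))

  scores <- matrix(stats::rnorm(n * L), n, L) %*% diag(score_sd, L)
  scores <- sweep(scores, 2, colMeans(scores))

  X <- vector("list", n)
  for (i in seq_len(n)) {
    V <- Reduce(`+`, lapply(seq_len(L), function(l) scores[i, l] * loadings[[l]]))
    base_i <- exp_map(mu_X, V)
    X[[i]] <- if (noise_sd_x > 0) exp_map(base_i, random_sym(R, noise_sd_x)) else base_i
  }

  u <- sweep(sweep(scores, 2, beta1, `*`), 2, beta0, `+`)
  if (noise_sd_y > 0) u <- u + matrix(stats::rnorm(n * L, 0, noise_sd_y), n, L)

  q_loadings <- if (L <= q) {
    qr.Q(qr(matrix(stats::rnorm(q * L), q, L)))[, seq_len(L), drop = FALSE]
  } else {
    m <- matrix(stats::rnorm(q * L), q, L)
    sweep(m, 2, sqrt(colSums(m^2)), `/`)
  }
  Y <- u %*% t(q_loadings)
  if (noise_sd_y > 0) Y <- Y + matrix(stats::rnorm(n * q, 0, noise_sd_y), n, q)

  structure(
    list(X = X, Y = Y, true_mu_X = mu_X, true_loadings = loadings,
         true_scores = scores, true_inner = list(beta0 = beta0, beta1 = beta1),
         q_loadings = q_loadings, noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
         seed = seed, n = n, R = R, L = L, q = q),
    class = "rpls_dataset"
  )
}

#' @export
print.rpls_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic Riemannian PLS dataset: n = %d subjects, R = %d, L = %d planted components, q = %d responses\n",
    x$n, x$R, x$L, x$q
  ))
  invisible(x)
}

#' Generate group-structured ROI time series with a phenotype table
#'
#' Emulates a two-group functional-imaging study: each subject's ROI time
#' series are Gaussian draws from a subject-specific target correlation
#' matrix.  The target is a common base correlation structure shifted by
#' `effect_size` on a designated edge set for the patient group, and by
#' `age_effect` times a standardised age covariate on a second edge set.
#' Targets are eigenvalue-floored and rescaled to stay valid correlation
#' matrices.
#'
#' @param n Number of subjects (groups are balanced).
#' @param R Number of ROIs.
#' @param T Number of time points (use `T >= R + 2` for full-rank sample
#'   correlations).
#' @param effect_size Shift applied to the group edge set (sign preserved).
#' @param seed Integer seed.
#' @param group_edges,age_edges Two-column matrices of (i, j) ROI pairs
#'   (defaults: edge 1-2 for group, edge 3-4 for age).
#' @param age_effect Shift per standard deviation of age (default 0.2).
#' @return A list with `timeseries` (list of `T x R` matrices), `phenotypes`
#'   (tibble: `subject_id`, `group`, `age`), `targets` (the per-subject
#'   correlation matrices), `group_edges`, `age_edges`, `roi_labels`.
#' @export
generate_group_timeseries <- function(n, R, T, effect_size, seed = NULL,
                                      group_edges = matrix(c(1, 2), 1),
                                      age_edges = matrix(c(3, 4), 1),
                                      age_effect = 0.2) {
  if (R < 4) stop("`R` must be at least 4 for the default edge sets", call. = FALSE)
  if (T < 3) stop("`T` must be at least 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  roi_labels <- sprintf("ROI%02d", seq_len(R))

  base <- stats::cov2cor(random_spd(R, c(0.5, 2)))
  edge_matrix <- function(edges) {
    E <- matrix(0, R, R)
    for (r in seq_len(nrow(edges))) {
      E[edges[r, 1], edges[r, 2]] <- 1
      E[edges[r, 2], edges[r, 1]] <- 1
    }
    E
  }
  E_group <- edge_matrix(group_edges)
  E_age <- edge_matrix(age_edges)

  group <- rep(c(0L, 1L), length.out = n)
  age <- stats::rnorm(n, 30, 8)
  age_z <- as.numeric(scale(age))

  to_correlation <- function(S) {
    S <- symmetrize(S)
    e <- eigen(S, symmetric = TRUE)
    S <- symmetrize(e$vectors %*% (pmax(e$values, 0.05) * t(e$vectors)))
    stats::cov2cor(S)
  }

  targets <- vector("list", n)
  timeseries <- vector("list", n)
  for (i in seq_len(n)) {
    Sigma <- to_correlation(base + effect_size * group[i] * E_group +
                              age_effect * age_z[i] * E_age)
    targets[[i]] <- Sigma
    ts <- matrix(stats::rnorm(T * R), T, R) %*% chol(Sigma)
    colnames(ts) <- roi_labels
    timeseries[[i]] <- ts
  }

  list(
    timeseries = timeseries,
    phenotypes = tibble::tibble(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = group,
      age = age
    ),
    targets = targets,
    group_edges = group_edges,
    age_edges = age_edges,
    roi_labels = roi_labels,
    seed = seed
  )
}
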