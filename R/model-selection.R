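# Stratified k-fold cross-validation, multivariate RMSE / R-squared, group
# classification metrics, and the one-standard-error choice of the number of
# latent components.

#' Stratified k-fold split
#'
#' Partitions `1..n` into `k` disjoint folds such that each stratum's members
#' are spread across folds to within one member.  Deterministic given `seed`.
#'
#' @param group_labels Length-`n` vector of stratum labels.
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed.
#' @return A list of `k` integer index vectors.
#' @export
stratified_kfold <- function(group_labels, k = 10L, seed = NULL) {
  n <- length(group_labels)
  if (k < 2 || k > n) stop("`k` must be between 2 and the number of observations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  folds <- vector("list", k)
  for (g in unique(group_labels)) {
    idx <- which(group_labels == g)
    # Balanced multiset of fold labels, randomly matched to members.
    labels <- sample(rep_len(seq_len(k), length(idx)))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[labels == f])
  }
  lapply(folds, sort)
}

#' Pooled multivariate RMSE
#'
#' Root mean squared error over all `m x q` entries of the response block;
#' with standardised responses this pools every response equally.
#'
#' @param Y,Yhat Matrices of equal shape.
#' @return A nonnegative scalar.
#' @export
multivariate_rmse <- function(Y, Yhat) {
  Y <- as.matrix(Y)
  Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("`Y` and `Yhat` must have equal shape", call. = FALSE)
  sqrt(mean((Y - Yhat)^2))
}

#' Binary classification metrics from continuous scores
#'
#' A subject is classified into the patient group when its predicted group
#' score exceeds zero (the standardised-response decision rule).  AUC uses
#' the rank (Mann-Whitney) formulation, with ties contributing one half.
#' With a single-class truth vector, sensitivity/specificity/AUC are
#' reported as `NA` rather than raising an error.
#'
#' @param scores Length-`m` numeric scores.
#' @param truth Length-`m` binary labels (1 = patient, 0 = control).
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `auc`.
#' @export
classification_metrics <- function(scores, truth) {
  scores <- as.numeric(scores)
  truth <- as.numeric(truth)
  if (length(scores) != length(truth)) stop("`scores` and `truth` must have equal length", call. = FALSE)
  if (!all(truth %in% c(0, 1))) stop("`truth` must be coded 0/1", call. = FALSE)
  pred <- as.numeric(scores > 0)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  acc <- mean(pred == truth)
  sens <- if (n1 > 0) sum(pred == 1 & truth == 1) / n1 else NA_real_
  spec <- if (n0 > 0) sum(pred == 0 & truth == 0) / n0 else NA_real_
  auc <- if (n1 > 0 && n0 > 0) {
    r <- rank(scores) # average ranks: ties contribute 1/2
    (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  tibble::tibble(accuracy = acc, sensitivity = sens, specificity = spec, auc = auc)
}

#' One-standard-error choice of the component count
#'
#' Let `K*` minimise the mean cross-validated RMSE.  The selected `K` is the
#' smallest component count whose mean RMSE is within one standard error of
#' the minimum: `rmse_mean[K] <= rmse_mean[K*] + rmse_se[K*]`.
#'
#' @param rmse_mean,rmse_se Equal-length numeric vectors indexed by `K`.
#' @return The selected integer `K` (always `<= K*`).
#' @export
select_k_one_se <- function(rmse_mean, rmse_se) {
  if (!length(rmse_mean)) stop("`rmse_mean` is empty", call. = FALSE)
  if (length(rmse_mean) != length(rmse_se)) {
    stop("`rmse_mean` and `rmse_se` must have equal length", call. = FALSE)
  }
  k_star <- which.min(rmse_mean)
  threshold <- rmse_mean[k_star] + rmse_se[k_star]
  which(rmse_mean <= threshold)[1]
}

# Coerce a response table to a numeric matrix, coding two-level
# character/factor/logical columns as 0/1 (alphabetical level order).
as_response_matrix <- function(Y) {
  if (is.matrix(Y)) {
    storage.mode(Y) <- "double"
    return(list(Y = Y, coding = list()))
  }
  Y <- as.data.frame(Y)
  coding <- list()
  for (nm in names(Y)) {
    col <- Y[[nm]]
    if (is.logical(col)) {
      coding[[nm]] <- c("FALSE", "TRUE")
      Y[[nm]] <- as.numeric(col)
    } else if (is.character(col) || is.factor(col)) {
      lev <- sort(unique(as.character(col)))
      if (length(lev) != 2) {
        stop(sprintf("column `%s` is categorical with %d levels; only binary categoricals are supported",
                     nm, length(lev)), call. = FALSE)
      }
      coding[[nm]] <- lev
      Y[[nm]] <- as.numeric(as.character(col) == lev[2])
    }
  }
  list(Y = as.matrix(Y), coding = coding)
}

#' Cross-validate a PLS model over the number of components
#'
#' Stratified k-fold cross-validation of the full pipeline.  For every fold,
#' the response block is standardised (mean 0, sd 1 per column) using
#' *training-fold* statistics only; for `model = "riemannian"` the Frechet
#' mean of the predictors is likewise recomputed on the training fold.  A
#' single NIPALS fit at `Kmax` provides the nested sequence of models for
#' `K = 1, ..., Kmax` (components are nested by deflation), the held-out
#' RMSE curve is aggregated over folds, and the one-standard-error rule
#' picks `k_selected`.  Classification metrics and R-squared are computed
#' from out-of-fold predictions at `k_selected`.
#'
#' @param X Predictors: a list of SPD/connectivity matrices, or an `n x p`
#'   numeric matrix (then `model` must be `"euclidean"`).
#' @param Y Response data frame or matrix (binary categoricals are coded
#'   0/1 before standardisation).
#' @param Kmax Largest component count on the grid `1..Kmax`.
#' @param folds Number of folds (default 10).
#' @param model Predictor construction: `"riemannian"` (tangent coordinates
#'   at the training Frechet mean), `"raw"` (strict upper triangle of each
#'   matrix), `"fisher"` (arctanh of the same entries), or `"euclidean"`
#'   (a plain feature matrix used as-is).
#' @param seed Integer seed for the fold split.
#' @param group Name (or index) of the binary response column used for
#'   stratification and classification; `NULL` disables both.
#' @param whiten,scale_offdiag,frechet_control Passed to the Riemannian
#'   linearisation (see [tnipals_fit()]).
#' @param store_fits Keep the per-fold `pls_fit` objects (for diagnostics).
#' @return An object of class `cv_result`; see [glance.cv_result()] and
#'   [tidy.cv_result()].
#' @export
cross_validate <- function(X, Y, Kmax, folds = 10L,
                           model = c("riemannian", "raw", "fisher", "euclidean"),
                           seed = NULL, group = NULL, whiten = FALSE,
                           scale_offdiag = sqrt(2), frechet_control = list(),
                           store_fits = FALSE) {
  model <- match.arg(model)
  resp <- as_response_matrix(Y)
  Ymat <- resp$Y
  n <- nrow(Ymat)
  q <- ncol(Ymat)

  if (model == "euclidean") {
    features <- as.matrix(X)
    if (nrow(features) != n) stop("`X` and `Y` must have matching rows", call. = FALSE)
  } else {
    if (!is.list(X) || length(X) != n) {
      stop("`X` must be a list of square matrices matching the rows of `Y`", call. = FALSE)
    }
    if (model %in% c("raw", "fisher")) {
      features <- do.call(rbind, lapply(X, function(F) {
        v <- upper_triangle_values(F)
        if (model == "fisher") {
          if (any(abs(v) >= 1)) stop("Fisher transform undefined for |r| >= 1", call. = FALSE)
          atanh(v)
        } else v
      }))
    }
  }

  group_col <- NULL
  if (!is.null(group)) {
    group_col <- if (is.character(group)) match(group, colnames(Ymat)) else as.integer(group)
    if (is.na(group_col) || group_col < 1 || group_col > q) {
      stop("`group` does not name a response column", call. = FALSE)
    }
    truth_all <- Ymat[, group_col]
    if (!all(truth_all %in% c(0, 1))) stop("the `group` column must be coded 0/1", call. = FALSE)
    strata <- truth_all
  } else {
    strata <- rep(1, n)
  }

  fold_idx <- stratified_kfold(strata, folds, seed)
  n_folds <- length(fold_idx)

  rmse_by_fold <- matrix(NA_real_, n_folds, Kmax)
  group_preds <- vector("list", n_folds)   # m x Kmax matrices of group scores
  resid_ss <- matrix(NA_real_, n_folds, Kmax)
  total_ss <- numeric(n_folds)
  fold_r2 <- matrix(NA_real_, n_folds, Kmax)
  fits <- if (store_fits) vector("list", n_folds)

  for (i in seq_len(n_folds)) {
    te <- fold_idx[[i]]
    tr <- setdiff(seq_len(n), te)
    ym <- colMeans(Ymat[tr, , drop = FALSE])
    ys <- apply(Ymat[tr, , drop = FALSE], 2, stats::sd)
    if (any(ys == 0)) {
      stop(sprintf("response column %d is constant in training fold %d", which(ys == 0)[1], i),
           call. = FALSE)
    }
    Ytr <- sweep(sweep(Ymat[tr, , drop = FALSE], 2, ym), 2, ys, `/`)
    Yte <- sweep(sweep(Ymat[te, , drop = FALSE], 2, ym), 2, ys, `/`)

    if (model == "riemannian") {
      pts_tr <- X[tr]
      fm <- do.call(frechet_mean, c(list(points = pts_tr), frechet_control))
      if (!fm$converged) {
        stop(sprintf("Frechet mean did not converge in training fold %d", i), call. = FALSE)
      }
      Ftr <- spd_tangent_coords(pts_tr, fm$mean, scale_offdiag, whiten)
      Fte <- spd_tangent_coords(X[te], fm$mean, scale_offdiag, whiten)
    } else {
      Ftr <- features[tr, , drop = FALSE]
      Fte <- features[te, , drop = FALSE]
    }

    if (Kmax > min(ncol(Ftr), length(tr) - 1)) {
      stop(sprintf("Kmax = %d exceeds min(p, n_train - 1) = %d", Kmax,
                   min(ncol(Ftr), length(tr) - 1)), call. = FALSE)
    }
    fit <- nipals_fit(Ftr, Ytr, Kmax)
    if (store_fits) fits[[i]] <- fit

    gp <- matrix(NA_real_, length(te), Kmax)
    total_ss[i] <- sum(Yte^2)  # training mean is 0 on the standardised scale
    for (k in seq_len(Kmax)) {
      pred <- pls_predict(fit, Fte, min(k, fit$K))
      rmse_by_fold[i, k] <- multivariate_rmse(Yte, pred)
      resid_ss[i, k] <- sum((Yte - pred)^2)
      fold_r2[i, k] <- 1 - resid_ss[i, k] / total_ss[i]
      if (!is.null(group_col)) gp[, k] <- pred[, group_col]
    }
    group_preds[[i]] <- gp
  }

  rmse_mean <- colMeans(rmse_by_fold)
  rmse_se <- apply(rmse_by_fold, 2, stats::sd) / sqrt(n_folds)
  k_min <- which.min(rmse_mean)
  k_selected <- select_k_one_se(rmse_mean, rmse_se)

  classification <- NULL
  if (!is.null(group_col)) {
    classification <- purrr::map_dfr(seq_len(n_folds), function(i) {
      te <- fold_idx[[i]]
      truth <- Ymat[te, group_col]
      if (length(unique(truth)) < 2) {
        tibble::tibble(fold = i, accuracy = NA_real_, sensitivity = NA_real_,
                       specificity = NA_real_, auc = NA_real_)
      } else {
        dplyr::bind_cols(tibble::tibble(fold = i),
                         classification_metrics(group_preds[[i]][, k_selected], truth))
      }
    })
  }

  r2_pooled <- 1 - sum(resid_ss[, k_selected]) / sum(total_ss)
  structure(
    list(
      rmse_by_fold = rmse_by_fold,
      rmse_mean = rmse_mean,
      rmse_se = rmse_se,
      k_min = k_min,
      k_selected = k_selected,
      classification = classification,
      r2_by_fold = fold_r2[, k_selected],
      r2_mean = mean(fold_r2[, k_selected]),
      r2_pooled = r2_pooled,
      folds = fold_idx,
      model = model,
      seed = seed,
      Kmax = Kmax,
      coding = resp$coding,
      fits = fits
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d-fold cross-validation (%s model), K grid 1..%d\n  k_min = %d, k_selected (one-SE) = %d\n  RMSE at k_selected = %.4f (SE %.4f); pooled R^2 = %.4f\n",
    length(x$folds), x$model, x$Kmax, x$k_min, x$k_selected,
    x$rmse_mean[x$k_selected], x$rmse_se[x$k_selected], x$r2_pooled
  ))
  if (!is.null(x$classification)) {
    m <- colMeans(x$classification[, -1], na.rm = TRUE)
    cat(sprintf("  classification (fold means): accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
                m["accuracy"], m["sensitivity"], m["specificity"], m["auc"]))
  }
  invisible(x)
}
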