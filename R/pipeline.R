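# End-to-end orchestration: standardise phenotypes -> cross-validated model
# selection -> fit at the selected K -> VIP permutation test -> network
# summary, with all artefacts written to an output directory.

#' Validated pipeline configuration
#'
#' Builds the configuration record for [run_pipeline()].  Unknown arguments
#' are rejected and every field is validated before any computation starts.
#'
#' @param x_path Predictor input (directory of CSVs or stacked-array prefix).
#' @param y_path Phenotype CSV path.
#' @param out_dir Output directory for artefacts.
#' @param mapping_path Optional ROI-to-network mapping CSV.
#' @param model One of `"riemannian"`, `"raw"`, `"fisher"`.
#' @param kmax Component grid upper end (default 10).
#' @param folds Cross-validation folds (default 10).
#' @param H Number of VIP permutations (default 200).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed (default 1).
#' @param group Name of the binary group column (default `"group"`; `NULL`
#'   disables stratification/classification).
#' @param whiten,scale_offdiag Vectorisation options (see [tnipals_fit()]).
#' @param mask_diagonal Assign p-value 1 to diagonal-derived tangent
#'   coordinates in the VIP test (default `TRUE`).
#' @param regularise_mode `"uniform"` or `"per-matrix"`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(x_path, y_path, out_dir, mapping_path = NULL,
                       model = "riemannian", kmax = 10L, folds = 10L,
                       H = 200L, alpha = 0.05, seed = 1L, group = "group",
                       whiten = FALSE, scale_offdiag = sqrt(2),
                       mask_diagonal = TRUE, regularise_mode = "uniform") {
  stopifnot(is.character(x_path), is.character(y_path), is.character(out_dir))
  model <- match.arg(model, c("riemannian", "raw", "fisher"))
  regularise_mode <- match.arg(regularise_mode, c("uniform", "per-matrix"))
  stopifnot(kmax >= 1, folds >= 2, H >= 1, alpha > 0, alpha < 1)
  structure(
    list(x_path = x_path, y_path = y_path, out_dir = out_dir,
         mapping_path = mapping_path, model = model, kmax = as.integer(kmax),
         folds = as.integer(folds), H = as.integer(H), alpha = alpha,
         seed = as.integer(seed), group = group, whiten = isTRUE(whiten),
         scale_offdiag = scale_offdiag, mask_diagonal = isTRUE(mask_diagonal),
         regularise_mode = regularise_mode),
    class = "run_config"
  )
}

pipeline_log <- function(con, stage, detail) {
  line <- sprintf("[%s] %s", stage, detail)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Loads and aligns the dataset, standardises phenotypes, cross-validates
#' the chosen model over `K = 1..kmax` with the one-standard-error rule,
#' refits at the selected `K` on the full dataset, runs the VIP permutation
#' test on the tangent coordinates, and (when a mapping is supplied)
#' averages coefficients at network level.  Writes `cv.json`, `fit.json`,
#' `vip.csv`, `edge_list.csv`, `network_summary.csv` (if mapped),
#' `MANIFEST.json` and `pipeline.log` to `out_dir`.  Deterministic given
#' the seed.  On a stage failure the partial artefacts are preserved and
#' the MANIFEST records the completion state.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the main in-memory results and
#'   `status = 0` on success, nonzero otherwise.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$out_dir, "pipeline.log"), "w")
  on.exit(close(log_con))
  completed <- character(0)
  manifest <- function(status) {
    jsonlite::write_json(
      list(status = status, completed = completed,
           config = unclass(config)[setdiff(names(config), "out_dir")],
           package_version = as.character(utils::packageVersion("rpls"))),
      file.path(config$out_dir, "MANIFEST.json"), auto_unbox = TRUE, null = "null"
    )
  }

  result <- tryCatch({
    pipeline_log(log_con, "load", sprintf("x=%s y=%s", config$x_path, config$y_path))
    ds <- load_dataset(config$x_path, config$y_path, config$mapping_path,
                       regularise = TRUE, regularise_mode = config$regularise_mode)
    n <- length(ds$X)
    R <- nrow(ds$X[[1]])
    pipeline_log(log_con, "load", sprintf("n=%d subjects, R=%d, %d regularised",
                                          n, R, sum(ds$regularised)))
    completed <- c(completed, "load")

    group <- if (!is.null(config$group) && config$group %in% colnames(ds$Y)) config$group else NULL

    pipeline_log(log_con, "cv", sprintf("model=%s kmax=%d folds=%d", config$model,
                                        config$kmax, config$folds))
    cv <- cross_validate(ds$X, ds$Y, Kmax = config$kmax, folds = config$folds,
                         model = config$model, seed = config$seed, group = group,
                         whiten = config$whiten, scale_offdiag = config$scale_offdiag)
    jsonlite::write_json(
      list(rmse_by_fold = cv$rmse_by_fold, rmse_mean = cv$rmse_mean,
           rmse_se = cv$rmse_se, k_min = cv$k_min, k_selected = cv$k_selected,
           r2_pooled = cv$r2_pooled, r2_mean = cv$r2_mean,
           classification = cv$classification, model = cv$model, seed = cv$seed),
      file.path(config$out_dir, "cv.json"), auto_unbox = TRUE, digits = NA, null = "null"
    )
    pipeline_log(log_con, "cv", sprintf("k_selected=%d (k_min=%d)", cv$k_selected, cv$k_min))
    completed <- c(completed, "cv")

    # Full-data fit at the selected K on standardised responses.
    Ystd <- scale(ds$Y)
    if (config$model == "riemannian") {
      fit <- tnipals_fit(ds$X, Ystd, K = cv$k_selected, whiten = config$whiten,
                         scale_offdiag = config$scale_offdiag)
      Xtan <- spd_tangent_coords(lapply(ds$X, as_spd), fit$mu_X,
                                 config$scale_offdiag, config$whiten)
      index <- sym_vec_index(R, ds$roi_labels %||% sprintf("ROI%03d", seq_len(R)))
      diagonal_idx <- if (config$mask_diagonal) index$idx[index$diagonal] else integer(0)
    } else {
      feats <- do.call(rbind, lapply(ds$X, function(F) {
        v <- upper_triangle_values(F)
        if (config$model == "fisher") atanh(v) else v
      }))
      fit <- tnipals_fit(feats, Ystd, K = cv$k_selected)
      Xtan <- feats
      strict <- sym_vec_index(R, ds$roi_labels %||% sprintf("ROI%03d", seq_len(R)))
      index <- strict[!strict$diagonal, ]
      index$idx <- seq_len(nrow(index))
      diagonal_idx <- integer(0)
    }
    write_rpls_fit(fit, file.path(config$out_dir, "fit.json"))
    completed <- c(completed, "fit")

    pipeline_log(log_con, "vip", sprintf("H=%d alpha=%g p=%d", config$H, config$alpha,
                                         ncol(Xtan)))
    vip_res <- vip_permutation_test(Xtan, Ystd, K = fit$K, H = config$H,
                                    alpha = config$alpha, seed = config$seed + 1L,
                                    diagonal_idx = diagonal_idx)
    vip_tbl <- dplyr::bind_cols(index[, c("idx", "row", "col", "label")],
                                tibble::tibble(vip = vip_res$vip,
                                               p_value = vip_res$p_values,
                                               p_adjusted = vip_res$p_adjusted,
                                               significant = vip_res$significant))
    readr::write_csv(vip_tbl, file.path(config$out_dir, "vip.csv"))
    pipeline_log(log_con, "vip", sprintf("%d significant connections", sum(vip_res$significant)))
    completed <- c(completed, "vip")

    # Coefficient matrix for the group column (or first response).
    resp_idx <- if (!is.null(group)) match(group, colnames(ds$Y)) else 1L
    beta <- fit$pls$coefficients[, resp_idx]
    coef_mat <- if (config$model == "riemannian") {
      coefficient_to_matrix(beta, R, config$scale_offdiag)
    } else {
      unvectorize_strict_upper(beta, R)
    }
    labels <- ds$roi_labels %||% sprintf("ROI%03d", seq_len(R))
    dimnames(coef_mat) <- list(labels, labels)

    edge_tbl <- vip_tbl[vip_tbl$row != vip_tbl$col, ]
    edges <- tibble::tibble(
      roi_i = labels[edge_tbl$row], roi_j = labels[edge_tbl$col],
      coefficient = coef_mat[cbind(edge_tbl$row, edge_tbl$col)],
      significant = edge_tbl$significant
    )
    readr::write_csv(edges, file.path(config$out_dir, "edge_list.csv"))
    completed <- c(completed, "edges")

    summary_obj <- NULL
    if (!is.null(ds$mapping)) {
      summary_obj <- network_average(coef_mat, ds$mapping)
      readr::write_csv(tidy(summary_obj), file.path(config$out_dir, "network_summary.csv"))
      completed <- c(completed, "network_summary")
      pipeline_log(log_con, "summary", sprintf("%d networks", length(summary_obj$networks)))
    }

    manifest(0L)
    pipeline_log(log_con, "done", "all stages completed")
    list(status = 0L, dataset = ds, cv = cv, fit = fit, vip = vip_res,
         vip_table = vip_tbl, network_summary = summary_obj)
  }, error = function(e) {
    pipeline_log(log_con, "error", conditionMessage(e))
    manifest(1L)
    list(status = 1L, error = conditionMessage(e))
  })
  invisible(result)
}

# Fold a strict-upper-triangle coefficient vector (row-major) into a
# symmetric matrix with zero diagonal.
unvectorize_strict_upper <- function(v, R) {
  S <- matrix(0, R, R)
  S[lower.tri(S)] <- v
  S <- t(S)
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}
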