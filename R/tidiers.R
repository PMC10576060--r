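# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PLS fit
#'
#' One row per predictor and component, with the weight and loading values.
#'
#' @param x A `pls_fit`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `term`, `weight`, `loading`.
#' @export
tidy.pls_fit <- function(x, ...) {
  p <- x$p
  K <- x$K
  tibble::tibble(
    component = rep(seq_len(K), each = p),
    term = rep(seq_len(p), K),
    weight = as.vector(x$weights),
    loading = as.vector(x$x_loadings)
  )
}

#' @rdname tidy.pls_fit
#' @export
glance.pls_fit <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, q = x$q, K = x$K,
                 requested_K = x$requested_K, truncated = x$truncated)
}

#' Tidy a Riemannian PLS fit
#'
#' Delegates to the embedded tangent-space PLS fit; for SPD predictors the
#' `term` index is augmented with the `(row, col)` matrix position of each
#' tangent coordinate.
#'
#' @param x An `rpls_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rpls_fit <- function(x, ...) {
  out <- tidy(x$pls)
  if (x$x_manifold$kind == "spd_affine_invariant") {
    idx <- sym_vec_index(x$x_manifold$dim)
    out <- dplyr::left_join(out, idx, by = c(term = "idx"))
  }
  out
}

#' @rdname tidy.rpls_fit
#' @export
glance.rpls_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(x_manifold = x$x_manifold$kind, y_manifold = x$y_manifold$kind,
                   whiten = x$vectorisation$whiten),
    glance(x$pls)
  )
}

#' Tidy cross-validation results
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble with one row per component count: `K`, `rmse_mean`,
#'   `rmse_se`, and flags for the RMSE-minimising and one-SE-selected `K`.
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(
    K = seq_along(x$rmse_mean),
    rmse_mean = x$rmse_mean,
    rmse_se = x$rmse_se,
    is_k_min = seq_along(x$rmse_mean) == x$k_min,
    is_k_selected = seq_along(x$rmse_mean) == x$k_selected
  )
}

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  cls <- if (!is.null(x$classification)) {
    m <- colMeans(x$classification[, c("accuracy", "sensitivity", "specificity", "auc")],
                  na.rm = TRUE)
    tibble::tibble(accuracy = m[["accuracy"]], sensitivity = m[["sensitivity"]],
                   specificity = m[["specificity"]], auc = m[["auc"]])
  } else {
    tibble::tibble(accuracy = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, auc = NA_real_)
  }
  dplyr::bind_cols(
    tibble::tibble(model = x$model, k_min = x$k_min, k_selected = x$k_selected,
                   rmse = x$rmse_mean[x$k_selected], rmse_se = x$rmse_se[x$k_selected],
                   r2 = x$r2_mean, r2_pooled = x$r2_pooled),
    cls
  )
}

#' Plot the cross-validated RMSE curve
#'
#' RMSE against the number of components with one-standard-error bars; the
#' dashed line marks the minimising `K`, the solid line the one-SE choice.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$rmse_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rmse_mean - .data$rmse_se,
                                      ymax = .data$rmse_mean + .data$rmse_se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_min, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$k_selected) +
    ggplot2::labs(x = "Number of latent components K",
                  y = "Cross-validated RMSE (standardised scale)",
                  title = sprintf("%s model: K* = %d, one-SE choice K = %d",
                                  object$model, object$k_min, object$k_selected)) +
    ggplot2::theme_minimal()
}

#' Tidy a VIP permutation-test result
#'
#' @param x A `vip_result`.
#' @param ... Unused.
#' @return A tibble with `predictor`, `vip`, `p_value`, `p_adjusted`,
#'   `significant`, `diagonal`.
#' @export
tidy.vip_result <- function(x, ...) {
  p <- length(x$vip)
  tibble::tibble(
    predictor = seq_len(p),
    vip = x$vip,
    p_value = x$p_values,
    p_adjusted = x$p_adjusted,
    significant = x$significant,
    diagonal = seq_len(p) %in% x$diagonal_idx
  )
}

#' @rdname tidy.vip_result
#' @export
glance.vip_result <- function(x, ...) {
  tibble::tibble(p = length(x$vip), H = x$H, alpha = x$alpha,
                 n_significant = sum(x$significant),
                 n_diagonal_masked = length(x$diagonal_idx),
                 n_redrawn = x$n_redrawn)
}

#' Plot VIP values with permutation significance
#'
#' @param object A `vip_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vip_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predictor, y = .data$vip,
                                   colour = .data$significant)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$predictor, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Tangent-coordinate predictor", y = "VIP",
                  colour = sprintf("FDR < %g", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Tidy a network-level coefficient summary
#'
#' @param x A `network_summary`.
#' @param ... Unused.
#' @return A long tibble over unordered network pairs: `network_i`,
#'   `network_j`, `mean_coefficient`, `top_quartile`, `within`.
#' @export
tidy.network_summary <- function(x, ...) {
  G <- length(x$networks)
  cells <- which(upper.tri(x$mean_coef, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    network_i = x$networks[cells[, "row"]],
    network_j = x$networks[cells[, "col"]],
    mean_coefficient = x$mean_coef[cells],
    top_quartile = x$top_mask[cells],
    within = cells[, "row"] == cells[, "col"]
  )
}

#' Plot a network-by-network coefficient heatmap
#'
#' Tiles are the averaged within/between-network coefficients; the top
#' quartile by absolute value is outlined.
#'
#' @param object A `network_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.network_summary <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network_i, y = .data$network_j,
                                   fill = .data$mean_coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[which(df$top_quartile), ], fill = NA,
                       colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Mean\ncoefficient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
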