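# Readers and writers for the on-disk formats: square CSV matrices, a
# stacked binary array container with a JSON sidecar, a directory-of-CSVs
# layout, phenotype and ROI-network mapping tables, and JSON fit bundles.

#' Write / read a square matrix as CSV
#'
#' The CSV is a square numeric table; ROI labels, when present, are written
#' as the header row.
#'
#' @param A A square numeric matrix.
#' @param path Output path.
#' @return `read_spd_csv` returns the matrix (with dimnames when the file
#'   has a header).
#' @export
write_spd_csv <- function(A, path) {
  df <- as.data.frame(A)
  if (is.null(colnames(A))) names(df) <- sprintf("V%d", seq_len(ncol(A)))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_spd_csv
#' @export
read_spd_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop(sprintf("`%s` is not a square matrix", path), call. = FALSE)
  labels <- colnames(df)
  if (all(grepl("^V[0-9]+$", labels))) labels <- NULL
  dimnames(m) <- if (!is.null(labels)) list(labels, labels)
  storage.mode(m) <- "double"
  m
}

#' Write / read a stacked array container
#'
#' Stores `n` square matrices as a flat little-endian float64 array
#' (`<prefix>.bin`, subject-major, each matrix row-major) with a JSON
#' sidecar (`<prefix>.json`) recording `n`, `R`, subject IDs and ROI labels.
#'
#' @param X A list of `R x R` matrices.
#' @param prefix Path prefix (without extension).
#' @param subjects Subject IDs (default `sub-001`, ...).
#' @param roi_labels Optional ROI labels.
#' @return `read_spd_stack` returns a list with `X`, `subjects`,
#'   `roi_labels`.
#' @export
write_spd_stack <- function(X, prefix, subjects = NULL, roi_labels = NULL) {
  n <- length(X)
  R <- nrow(X[[1]])
  subjects <- subjects %||% sprintf("sub-%03d", seq_len(n))
  stopifnot(length(subjects) == n, all(vapply(X, nrow, 1L) == R))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (A in X) writeBin(as.numeric(t(A)), con, size = 8, endian = "little")
  sidecar <- list(n = n, R = R, subjects = subjects,
                  roi_labels = roi_labels, storage = "float64/little-endian/row-major")
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE, null = "null")
  invisible(prefix)
}

#' @rdname write_spd_stack
#' @export
read_spd_stack <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- sidecar$n
  R <- sidecar$R
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n * R * R, size = 8, endian = "little")
  if (length(vals) != n * R * R) stop("stacked array is shorter than its sidecar declares", call. = FALSE)
  X <- lapply(seq_len(n), function(i) {
    m <- matrix(vals[((i - 1) * R * R + 1):(i * R * R)], R, R, byrow = TRUE)
    if (!is.null(sidecar$roi_labels)) dimnames(m) <- list(sidecar$roi_labels, sidecar$roi_labels)
    m
  })
  list(X = X, subjects = sidecar$subjects, roi_labels = sidecar$roi_labels)
}

#' Write / read a directory of per-subject matrix CSVs
#'
#' One `<subject>.csv` per subject plus a `manifest.json` listing subject
#' order and ROI labels.
#'
#' @param X A list of square matrices.
#' @param dir Directory (created if absent).
#' @param subjects Subject IDs.
#' @param roi_labels Optional ROI labels.
#' @return `read_spd_dir` returns a list with `X`, `subjects`, `roi_labels`.
#' @export
write_spd_dir <- function(X, dir, subjects = NULL, roi_labels = NULL) {
  n <- length(X)
  subjects <- subjects %||% sprintf("sub-%03d", seq_len(n))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n)) {
    A <- X[[i]]
    if (!is.null(roi_labels)) dimnames(A) <- list(roi_labels, roi_labels)
    write_spd_csv(A, file.path(dir, paste0(subjects[i], ".csv")))
  }
  jsonlite::write_json(list(subjects = subjects, roi_labels = roi_labels),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname write_spd_dir
#' @export
read_spd_dir <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    subjects <- manifest$subjects
  } else {
    files <- sort(list.files(dir, pattern = "\\.csv$"))
    subjects <- sub("\\.csv$", "", files)
    manifest <- list(roi_labels = NULL)
  }
  X <- lapply(subjects, function(s) read_spd_csv(file.path(dir, paste0(s, ".csv"))))
  roi_labels <- manifest$roi_labels %||% rownames(X[[1]])
  list(X = X, subjects = subjects, roi_labels = roi_labels)
}

#' Load and align a study dataset
#'
#' Reads predictors (a stacked-array prefix or a directory of CSVs), the
#' phenotype CSV, and an optional ROI-to-network mapping CSV.  Phenotype
#' rows are aligned to predictor order by `subject_id` (an error names any
#' subject missing from the table), binary categorical phenotype columns
#' are coded 0/1, and standardisation statistics are computed and stored.
#' SPD validation is applied with a per-subject report; failures are
#' regularised via [regularize_dataset()] when `regularise` is `TRUE`,
#' otherwise they are an error.
#'
#' @param x_path Directory of per-subject CSVs or a stacked-array prefix.
#' @param y_path Phenotype CSV with a `subject_id` column.
#' @param mapping_path Optional CSV with columns `roi_label`, `network`.
#' @param regularise Apply `F + I` when SPD validation fails
#'   (default `TRUE`, uniform mode).
#' @param regularise_mode Passed to [regularize_dataset()].
#' @return A list with `X`, `subjects`, `roi_labels`, `phenotypes` (aligned
#'   tibble), `Y` (coded numeric matrix), `y_center`, `y_scale`, `coding`,
#'   `mapping`, `regularised`.
#' @export
load_dataset <- function(x_path, y_path, mapping_path = NULL,
                         regularise = TRUE, regularise_mode = "uniform") {
  if (!dir.exists(x_path) && !file.exists(paste0(x_path, ".json"))) {
    stop(sprintf("predictor input `%s` not found (expected a directory or a stack prefix)",
                 x_path), call. = FALSE)
  }
  xd <- if (dir.exists(x_path)) read_spd_dir(x_path) else read_spd_stack(x_path)

  pheno <- readr::read_csv(y_path, show_col_types = FALSE, progress = FALSE)
  if (!"subject_id" %in% names(pheno)) {
    stop("phenotype table must contain a `subject_id` column", call. = FALSE)
  }
  pos <- match(xd$subjects, pheno$subject_id)
  if (anyNA(pos)) {
    stop(sprintf("subject `%s` is missing from the phenotype table",
                 xd$subjects[which(is.na(pos))[1]]), call. = FALSE)
  }
  pheno <- pheno[pos, , drop = FALSE]

  spd_ok <- vapply(xd$X, is_spd, logical(1))
  regularised <- rep(FALSE, length(xd$X))
  if (!all(spd_ok)) {
    if (!regularise) {
      stop(sprintf("subject `%s` failed SPD validation (and %d other(s)); enable `regularise`",
                   xd$subjects[which(!spd_ok)[1]], sum(!spd_ok) - 1L), call. = FALSE)
    }
    reg <- regularize_dataset(xd$X, regularise_mode)
    xd$X <- reg$X
    regularised <- reg$regularised
  }

  resp <- as_response_matrix(pheno[setdiff(names(pheno), "subject_id")])
  y_center <- colMeans(resp$Y)
  y_scale <- apply(resp$Y, 2, stats::sd)

  mapping <- NULL
  if (!is.null(mapping_path)) {
    mapping <- readr::read_csv(mapping_path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("roi_label", "network") %in% names(mapping))) {
      stop("mapping CSV needs columns `roi_label` and `network`", call. = FALSE)
    }
  }

  list(X = xd$X, subjects = xd$subjects, roi_labels = xd$roi_labels,
       phenotypes = tibble::as_tibble(pheno), Y = resp$Y,
       y_center = y_center, y_scale = y_scale, coding = resp$coding,
       mapping = mapping, regularised = regularised)
}

# --- fit serialisation -------------------------------------------------------

fit_to_list <- function(fit) {
  pls <- fit$pls
  list(
    type = "rpls_fit",
    x_manifold = unclass(fit$x_manifold),
    y_manifold = unclass(fit$y_manifold),
    mu_X = fit$mu_X,
    mu_Y = fit$mu_Y,
    vectorisation = fit$vectorisation,
    K = fit$K,
    n = fit$n,
    pls = list(
      K = pls$K, requested_K = pls$requested_K,
      weights = pls$weights, y_weights = pls$y_weights,
      x_loadings = pls$x_loadings, y_loadings = pls$y_loadings,
      x_scores = pls$x_scores, y_scores = pls$y_scores,
      inner_coeffs = pls$inner_coeffs,
      x_means = pls$x_means, y_means = pls$y_means,
      deflate_y = pls$deflate_y, truncated = pls$truncated,
      n = pls$n, p = pls$p, q = pls$q,
      coefficients = pls$coefficients
    )
  )
}

#' Serialise / restore a Riemannian PLS fit as JSON
#'
#' The bundle holds every matrix of the fit at full double precision
#' (round-trip exact to write-read-write byte identity).
#'
#' @param fit An `rpls_fit`.
#' @param path Output `.json` path.
#' @return `read_rpls_fit` returns the restored `rpls_fit`.
#' @export
write_rpls_fit <- function(fit, path) {
  stopifnot(inherits(fit, "rpls_fit"))
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_rpls_fit
#' @export
read_rpls_fit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  pls <- raw$pls
  pls_fit <- structure(
    list(
      K = as.integer(pls$K), requested_K = as.integer(pls$requested_K),
      weights = as_mat(pls$weights), y_weights = as_mat(pls$y_weights),
      x_loadings = as_mat(pls$x_loadings), y_loadings = as_mat(pls$y_loadings),
      x_scores = as_mat(pls$x_scores), y_scores = as_mat(pls$y_scores),
      inner_coeffs = as.numeric(pls$inner_coeffs),
      x_means = as.numeric(pls$x_means), y_means = as.numeric(pls$y_means),
      deflate_y = pls$deflate_y, truncated = pls$truncated,
      n = as.integer(pls$n), p = as.integer(pls$p), q = as.integer(pls$q),
      coefficients = as_mat(pls$coefficients)
    ),
    class = "pls_fit"
  )
  x_man <- structure(list(kind = raw$x_manifold$kind, dim = as.integer(raw$x_manifold$dim)),
                     class = "rpls_manifold")
  y_man <- structure(list(kind = raw$y_manifold$kind, dim = as.integer(raw$y_manifold$dim)),
                     class = "rpls_manifold")
  structure(
    list(
      x_manifold = x_man, y_manifold = y_man,
      mu_X = if (x_man$kind == "spd_affine_invariant") as_mat(raw$mu_X) else as.numeric(raw$mu_X),
      mu_Y = if (y_man$kind == "spd_affine_invariant") as_mat(raw$mu_Y) else as.numeric(raw$mu_Y),
      vectorisation = raw$vectorisation,
      pls = pls_fit,
      K = as.integer(raw$K),
      n = as.integer(raw$n)
    ),
    class = "rpls_fit"
  )
}
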