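Package: rpls
Title: Riemannian Partial Least Squares for Symmetric Positive Definite Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Partial least squares regression for predictors (or responses) that
    live on the manifold of symmetric positive definite matrices under the
    affine-invariant geometry, as used for functional-connectivity analysis.
    Provides the tangent-space NIPALS (tNIPALS) fitting algorithm, Frechet-mean
    computation by gradient descent, variable-importance-in-projection (VIP)
    permutation inference with false-discovery-rate control, stratified
    cross-validation with the one-standard-error rule, connectivity-matrix
    utilities (regularisation, Fisher transform, network-level coefficient
    summaries), and a seeded synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
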