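---
title: "Riemannian partial least squares for SPD matrices: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Riemannian partial least squares for SPD matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpls)
```

## The problem

Functional connectivity is usually summarised as the Pearson correlation
matrix between regional fMRI time series. A full-rank correlation matrix is
symmetric positive definite (SPD), and the set of `R x R` SPD matrices is
not a vector space: it is a convex cone, and under the affine-invariant
metric it is a complete Riemannian manifold of non-positive curvature.
Feeding the upper triangle of such matrices into a linear method treats
them as unconstrained coordinates and ignores that structure. This package
implements partial least squares (PLS) regression for data blocks that live
on that manifold, so that connectivity matrices can predict multivariate
phenotypes (and vice versa) while respecting positive definiteness.

## The geometry

For SPD matrices `A`, `B` and symmetric tangent matrices `U`, `V` at `A`,
the package uses the affine-invariant structure:

* metric: `g_A(U, V) = Tr(U A^-1 V A^-1)`;
* distance: `d(A, B)^2 = sum_r log(sigma_r)^2`, `sigma_r` the eigenvalues of
  `A^{-1/2} B A^{-1/2}`;
* exponential map: `Exp_A(U) = A^{1/2} expm(A^{-1/2} U A^{-1/2}) A^{1/2}`;
* logarithm map: `Log_A(B) = A^{1/2} logm(A^{-1/2} B A^{-1/2}) A^{1/2}`.

All matrix functions (powers, `expm`, `logm`) are computed through the
symmetric eigendecomposition with re-symmetrisation of the result; this is
exact for symmetric input and numerically stable. The metric is invariant
under congruence `A -> G A G^T` for any invertible `G`, which the test
suite checks numerically for distance, metric, and mean.

The Fréchet mean `mu = argmin sum_i d(X_i, mu)^2` is computed by gradient
descent: `mu <- Exp_mu(step/n * sum_i Log_mu(X_i))`. The literature
typically cites gradient descent without hyper-parameters, so the defaults
here are package choices, exposed as arguments: `step = 1` (on a Hadamard
manifold with this objective the unit step is the standard Karcher
iteration and converges in a handful of iterations in practice),
`tol = 1e-8` on the Frobenius norm of the mean tangent vector,
`max_iter = 100`, and initialisation at the arithmetic mean of the inputs
with eigenvalues floored to keep it positive definite. Non-convergence is
reported as a flag, not an error, and the per-iteration objective is
returned so its monotone decrease can be verified.

A matrix is accepted as SPD when its smallest eigenvalue exceeds `1e-10`
times its largest — a scale-free criterion — and inputs are symmetrised as
`(A + A^T)/2` before validation to absorb round-trip I/O noise.

## The model and tNIPALS

Classical two-block PLS posits scores `T`, `U`, loadings `P`, `Q` with
`X = T P' + E`, `Y = U Q' + F` and a diagonal inner relation `U = T B + H`.
The Riemannian generalisation replaces the linear outer relationships with
geodesic ones: each observation is `Exp` of a loading combination of
tangent vectors at the Fréchet mean, perturbed by tangent noise, while the
inner relation between scalar scores stays linear.

Fitting is by **tNIPALS**: compute the Fréchet mean of each block, map
every observation into the mean's tangent space with the Riemannian
logarithm, vectorise symmetric tangents, and run classical NIPALS on the
coordinates. Prediction log-maps new predictors at the *training* mean
(never recomputed, so prediction cannot peek at test data), applies the
tangent-space regression, and for a manifold-valued response maps back
with `Exp` at the training response mean. When both blocks are Euclidean
the whole construction collapses to standard PLS; in this implementation
the collapse is exact in floating point, because for a Euclidean block the
log-map at the mean followed by NIPALS's column-centring *is*
column-centring, so the raw coordinates are passed straight through.

### NIPALS details

The inner loop iterates `w = X'u/|X'u|`, `t = Xw`, `c = Y't/|Y't|`,
`u = Yc` to convergence of `t` (one pass for a univariate response),
then deflates `X <- X - t p'` with `p = X't/t't` and, by default,
`Y <- Y - b t c'` with `b = u't/t't`. Two details matter:

* the response weight `c` is normalised to unit length. With that
  convention `b t c'` equals the projection of the current `Y` on `t`, the
  deflation is exact, and at `K = rank(X)` the fitted values coincide with
  the least-squares projection — which the test suite asserts against a
  dense `lm.fit` oracle. With an unnormalised `c` the inner slope becomes
  `b = c'c` and the deflation over- or under-shoots; that variant fails
  the least-squares equivalence and is not offered.
* each weight vector is sign-fixed so its largest-magnitude entry is
  positive, making output deterministic across platforms.

Columns are centred internally and never scaled; phenotype responses are
standardised upstream (mean 0, sd 1, binary variables coded 0/1 first).
If deflation exhausts the predictor block before `K` components, the fit
truncates with a `truncated` flag rather than an error — this is the
normal outcome on noiseless low-rank data.

### Vectorisation of symmetric tangents

A symmetric `R x R` tangent has `R(R+1)/2` free coordinates (780 at
`R = 39`, 6786 at `R = 116`). The package flattens the upper triangle
row-major and multiplies off-diagonal entries by `sqrt(2)` by default, so
the Euclidean dot product of coordinate vectors equals the Frobenius inner
product `Tr(UV)` of the matrices. Whether to duplicate or scale
off-diagonals is genuinely open — it changes the weight geometry and hence
VIP — so the scale is an exposed argument (`scale_offdiag = 1` gives the
unscaled half-vectorisation), with `sqrt(2)` as the default because it
preserves the tangent inner product.

A second open choice is the inner product NIPALS uses on tangents. The
default runs plain Euclidean NIPALS on the vectorised log-mapped data (the
most literal tangent-space reading). An optional `whiten = TRUE` first
maps `U -> mu^{-1/2} U mu^{-1/2}`, after which the Frobenius product equals
the affine-invariant metric at the mean; this makes the entire fit exactly
equivariant under congruence transformations of the data, a property the
test suite checks on cross-validated RMSE. Both paths are tested; whitening
is off by default.

Tangent data at the Fréchet mean are only approximately column-centred, so
NIPALS's internal centring is deliberately left on for them.

## VIP inference

The variable-importance-in-projection statistic for predictor `j` is
`VIP_j = sqrt( p / Rd(Y,T) * sum_k Rd(Y,t_k) w_jk^2 )` with
`Rd(Y,t) = mean_i cor(Y_i, t)^2`. Because weights are unit-norm,
`sum_j VIP_j^2 = p` identically — asserted for every model in the test
suite. Significance is assessed by permutation: for each predictor, its
tangent-coordinate column is permuted `H = 200` times (the predictors
NIPALS actually sees), the model is refitted *at the same `K`* (the
selection is not re-run per permutation), and the raw p-value is the
fraction of permuted VIPs strictly exceeding the observed one. The
p-values therefore sit on the grid `{0, 1/H, ..., 1}` and can be exactly
zero; an `add_one` flag gives the `(count+1)/(H+1)` variant for users who
need strictly positive values. P-values are Benjamini–Hochberg adjusted
(via `stats::p.adjust`) and thresholded at `alpha = 0.05`.

Connectivity diagonals are identically one, hence uninformative, and are
masked to p-value 1 a priori. For the Riemannian model the predictors are
tangent coordinates whose diagonal-derived entries are *not* constant, so
the masking of those coordinates is an interpretable convention rather
than a necessity; it is on by default (`mask_diagonal`) and can be
disabled. A `shared_permutations` flag reuses one permutation set across
predictors as a documented, off-by-default cost-saving approximation.

## Model selection and evaluation

Ten-fold cross-validation stratified by subject group scans
`K = 1..Kmax`. All statistics that could leak — response means and
standard deviations, the Fréchet mean of the predictors — are recomputed
on each training fold only (a test perturbs held-out subjects and asserts
the fitted fold model is unchanged). A single NIPALS fit at `Kmax` per fold
supplies the whole nested component sequence. The multivariate RMSE pools
all response entries equally on the standardised scale. `K` is chosen by
the one-standard-error rule: the smallest `K` whose mean RMSE is within
`sd/sqrt(folds)` of the minimum. Classification uses the standardised
group score: predicted patient if the score exceeds zero; accuracy,
sensitivity, specificity and rank-formulation (Mann–Whitney) AUC with ties
counted one half are reported per fold at the selected `K`, from
out-of-fold predictions (the alternative — refitting on the full data —
is not used, so the reported metrics are honest test-set quantities).
R-squared is reported both pooled over held-out folds
(`1 - sum|Y - Yhat|^2 / sum|Y - Ybar_train|^2`) and as a per-fold mean.

Euclidean comparator models use the strict upper triangle of each
connectivity matrix (`raw`), or its `arctanh` (`fisher`). The diagonal is
excluded there because it is constant and has zero variance after
centring; the `R(R+1)/2` count retains the diagonal only as a reporting
convention.

When any connectivity matrix in a dataset is rank-deficient, the `F + I`
regularisation (which shifts every eigenvalue up by exactly one) is by
default applied to *all* matrices of that dataset, so every subject shares
the same diagonal and geometry; a `per-matrix` mode regularises only the
failing matrices for users who want the literal minimal intervention.

## The synthetic generator

`generate_rpls_dataset()` draws from the forward model itself: a random
SPD base point with eigenvalues in `[0.5, 2]`, `L` tangent loadings
orthonormalised under the vectorised (Frobenius) inner product, centred
Gaussian scores with non-increasing standard deviations (default
`0.4 * 0.75^(l-1)`, keeping draws in a moderate neighbourhood of the mean
where the tangent approximation is good), tangent noise injected at the
noiseless point as a symmetric matrix with i.i.d. Gaussian entries, a
linear inner relation with Gaussian noise, and Euclidean responses through
unit-norm response loadings. One `noise_sd_y` scales both the
inner-relation noise and the response noise. All randomness flows from a
single integer seed in a fixed draw order, so regeneration is exact.

`generate_group_timeseries()` emulates a two-group imaging study: subject
time series are Gaussian draws from subject-specific target correlation
matrices, built from a common base structure shifted on a designated edge
set by the group effect and on a second edge set by a standardised
age-like covariate, then eigenvalue-floored and rescaled to stay valid
correlations.

What these generators do *not* emulate: autocorrelated BOLD noise, motion
artefacts, site effects, or heavy-tailed phenotypes. Passing tests
therefore demonstrate correctness of the algorithms under the stated
model, not robustness to real fMRI preprocessing choices.

## Verification at a glance

The test suite and `scripts/acceptance.R` verify, among other things:
Exp/Log inversion and metric-distance consistency on random SPD instances
at `R` in {3, 6, 10}; congruence equivariance of distance, metric and
Fréchet mean; closed-form means (geodesic midpoint, commuting families);
full-rank PLS against a dense least-squares oracle; bit-for-bit Euclidean
reduction of tNIPALS; the VIP sum-of-squares identity; near-uniform null
permutation p-values with FDR false-positive control and power on planted
signal (20 replicates at `n = 50`, `p = 10`, `H = 200`); and recovery of
the planted loading subspace with correct one-SE component selection on 20
seeded replicates at `n = 100`, `R = 6`, `L = 2`, low noise. These problem
sizes were chosen to exercise each property at meaningful scale while
keeping the whole suite fast enough to run routinely.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
ds <- generate_rpls_dataset(n = 100, R = 6, L = 2, q = 2,
                            noise_sd_x = 0.05, noise_sd_y = 0.05, seed = 11)

cv <- cross_validate(ds$X, ds$Y, Kmax = 5, folds = 10,
                     model = "riemannian", seed = 2)
glance(cv)
autoplot(cv)

fit <- tnipals_fit(ds$X, ds$Y, K = cv$k_selected)
Xtan <- do.call(rbind, lapply(ds$X, function(A)
  vectorize_sym(log_map(fit$mu_X, A))))
idx <- sym_vec_index(6)
vip_res <- vip_permutation_test(Xtan, scale(ds$Y), K = fit$K, H = 200,
                                seed = 3, diagonal_idx = idx$idx[idx$diagonal])
tidy(vip_res)
```

## Known limitations

* Only the Euclidean and affine-invariant SPD geometries are implemented;
  log-Euclidean and Bures–Wasserstein alternatives are out of scope.
* The direct (non-tangent) Riemannian NIPALS generalisation is not
  offered: it is computationally heavy and known not to converge beyond
  very small samples.
* The VIP statistic acts on tangent coordinates and aggregates over the
  full multivariate response; it does not attribute significance to
  individual response variables.
* Per-predictor permutation costs `p * H` refits; for large atlases
  (`p = 6786`) this is substantial, and the shared-permutation
  approximation or fewer permutations trade exactness for time.
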