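# Fixtures built in code: random SPD matrices, symmetric tangents, and small
# regression datasets.  Everything is generated under explicit seeds.

make_spd <- function(R, seed = NULL, eig_range = c(0.5, 2)) {
  if (!is.null(seed)) set.seed(seed)
  random_spd(R, eig_range)
}

make_sym <- function(R, sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- R * (R + 1) / 2
  unvectorize_sym(rnorm(d, 0, sd), R, scale_offdiag = 1)
}

# A linear-model regression dataset Y = X B + noise.
make_regression <- function(n, p, q, noise_sd = 0.1, rank = p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(rnorm(p * rank), p, rank) %*% matrix(rnorm(rank * q), rank, q) / rank
  Y <- X %*% B + noise_sd * matrix(rnorm(n * q), n, q)
  list(X = X, Y = Y, B = B)
}

frob <- function(M) sqrt(sum(M * M))

# Mean absolute cosine of principal angles between the column spans of two
# (vectorised) loading sets.
subspace_mean_cosine <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  mean(svd(crossprod(qa, qb))$d)
}
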