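# Independent brute-force oracles and fixture builders shared across tests.
# These deliberately avoid the package's own computational paths.

# chi-square by explicit observed-vs-expected summation
chi2_oe_oracle <- function(a, b, c, d) {
  obs <- matrix(c(a, c, b, d), 2, 2)
  n <- sum(obs)
  expected <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expected)^2 / expected)
}

# AuROC by O(n^2) enumeration of positive x negative pairs, ties = 1/2
auroc_pair_oracle <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Global-minimum k=2 inertia by exhaustive enumeration of all two-block
# partitions (bitmask over n <= 12 points, both blocks non-empty).
best_partition_inertia_k2 <- function(X) {
  n <- nrow(X)
  stopifnot(n <= 14)
  w <- function(M) sum(sweep(M, 2, colMeans(M))^2)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {   # point n fixed in block B: halves the space
    inblock <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    A <- X[inblock, , drop = FALSE]
    B <- X[!inblock, , drop = FALSE]
    best <- min(best, w(A) + w(B))
  }
  best
}

# Tukey hinges by explicit sort-and-index arithmetic
hinges_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  half <- function(v) {
    m <- length(v)
    if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
  }
  lower <- x[1:ceiling(n / 2)]
  upper <- x[(floor(n / 2) + 1):n]
  c(median = half(x), iqr = half(upper) - half(lower))
}

# two well-separated Gaussian blobs in 6-D subscore-like space
make_blobs <- function(n_per, mu1, mu2, sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per * 6, rep(mu1, each = n_per), sd), n_per, 6),
    matrix(rnorm(n_per * 6, rep(mu2, each = n_per), sd), n_per, 6))
  list(X = X, truth = rep(1:2, each = n_per))
}

# small hand-buildable cohort data frame (valid by construction)
toy_cohort <- function(n = 8, seed = 1) {
  g <- generate_cohort(generator_config(n = n, seed = seed))
  g$cohort
}

# printed per-fold reference centroid summaries (median, IQR), frozen
reference_fold_summary_expected <- function() {
  list(
    cdi1_median = c(2.41, 2.65, 3.33, 1.47, 0.47, 1.98),
    cdi1_iqr    = c(0.09, 0.12, 0.11, 0.14, 0.04, 0.05),
    cdi0_median = c(0.85, 0.55, 1.24, 0.69, 0.01, 1.31),
    cdi0_iqr    = c(0.07, 0.04, 0.06, 0.04, 0.00, 0.02))
}
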