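# Independent oracles used across the suite. Each recomputes a quantity by
# a different route than the implementation it checks.

# Exact expectation of a statistic of the observed counts by enumerating
# every ordered iid draw (S^n outcomes) -- a different route than the
# composition-based enumeration in the package.
oracle_expectation_iid <- function(p, n, statistic) {
  S <- length(p)
  draws <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  total <- 0
  for (i in seq_len(nrow(draws))) {
    idx <- draws[i, ]
    prob <- prod(p[idx])
    cnt <- tabulate(idx, nbins = S)
    total <- total + prob * statistic(cnt[cnt > 0])
  }
  total
}

# Z_r through the untransformed factorial form
# n^{r+1} (n-r-1)!/n! * sum_s p-hat_s prod_{j=0}^{r-1} (1 - p-hat_s - j/n),
# algebraically equal to the product form used by the package but computed
# along a different path.
oracle_z_factorial <- function(counts, r) {
  n <- sum(counts)
  stopifnot(r <= n - 1)
  phat <- counts / n
  lead <- exp((r + 1) * log(n) + lgamma(n - r) - lgamma(n + 1))
  lead * sum(vapply(phat, function(ph) ph * prod(1 - ph - (0:(r - 1)) / n),
                    numeric(1)))
}

# expected species count in a subsample of size m (rarefaction), written
# directly from hypergeometric inclusion probabilities
oracle_rarefied_richness <- function(counts, m) {
  n <- sum(counts)
  sum(1 - exp(lchoose(n - counts, m) - lchoose(n, m)))
}

# generalized jackknife of order k: the linear combination of rarefied
# richnesses E_{n}, E_{n-1}, ..., E_{n-k} that cancels bias terms
# 1/m, ..., 1/m^k, found by solving the (scaled) Vandermonde system.
# Numerically reliable for small n only; use n <= ~60.
oracle_jackknife <- function(counts, k) {
  n <- sum(counts)
  A <- rbind(rep(1, k + 1),
             t(sapply(seq_len(k), function(j) ((n - 0:k) / n)^(-j))))
  coefs <- solve(A, c(1, rep(0, k)))
  sum(coefs * vapply(0:k, function(i) oracle_rarefied_richness(counts, n - i),
                     numeric(1)))
}

# random community on the S-simplex
random_community <- function(S) {
  w <- stats::rexp(S)
  community(w / sum(w))
}

# fixed grid of test communities: 5 probability vectors per richness
community_grid <- function() {
  list(
    community(c(0.5, 0.5)),
    community(c(2 / 3, 1 / 3)),
    community(c(0.9, 0.1)),
    community(c(0.75, 0.25)),
    community(c(0.55, 0.45)),
    community(c(1 / 3, 1 / 3, 1 / 3)),
    community(c(0.5, 0.3, 0.2)),
    community(c(0.6, 0.3, 0.1)),
    community(c(0.8, 0.15, 0.05)),
    community(c(0.45, 0.35, 0.2))
  )
}

# plug-in estimator of zeta_r from observed counts
plugin_zeta <- function(counts, r) {
  phat <- counts / sum(counts)
  sum(phat * (1 - phat)^r)
}

# vectorized Z_r over the columns of a count matrix (species x replicates);
# zero counts contribute nothing since p-hat = 0
z_estimate_matrix <- function(cnts, n, r) {
  phat <- cnts / n
  f <- matrix(1, nrow = nrow(cnts), ncol = ncol(cnts))
  for (j in seq_len(r)) f <- f * (1 - (cnts - 1) / (n - j))
  colSums(phat * f)
}
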