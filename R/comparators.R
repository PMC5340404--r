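#' HCDT (Tsallis) entropy
#'
#' \deqn{{}^{q}T = \frac{\sum_s p_s^q - 1}{1 - q}, \qquad q \ge 0,}
#' with the Shannon limit \eqn{-\sum_s p_s \log p_s} at \eqn{q = 1}
#' (applied within `1e-9` of 1). Special cases: \eqn{q = 0} gives
#' \eqn{S - 1} (richness minus one) and \eqn{q = 2} gives
#' \eqn{1 - \sum p_s^2 = \zeta_1}, the link between the HCDT family and
#' generalized Simpson's entropy.
#'
#' @param x A [community] (or anything [as_community()] accepts).
#' @param q Order(s) of the entropy, >= 0 (real-valued).
#' @return HCDT entropy value(s).
#' @export
hcdt_entropy <- function(x, q) {
  p <- community_probs(x)
  vapply(q, function(qi) {
    check_q(qi)
    if (abs(qi - 1) < 1e-9) {
      -sum(p * log(p))
    } else {
      (sum(p^qi) - 1) / (1 - qi)
    }
  }, numeric(1))
}

#' Hill diversity (effective number of species of HCDT entropy)
#'
#' \deqn{{}^{q}D^{T} = \left(\sum_s p_s^q\right)^{1/(1-q)},}
#' with \eqn{\exp({}^{1}T)} at \eqn{q = 1}. Equals `S` at \eqn{q = 0}, the
#' inverse Simpson concentration \eqn{1/\sum p_s^2} at \eqn{q = 2}, and is
#' non-increasing in `q` (constant at `S` only for the uniform community).
#' Computed by plugging in the supplied proportions; when those are sample
#' proportions this is the plug-in (negatively biased) Hill number.
#'
#' @inheritParams hcdt_entropy
#' @return Effective number(s) of species, >= 1.
#' @export
hill_diversity <- function(x, q) {
  p <- community_probs(x)
  vapply(q, function(qi) {
    check_q(qi)
    if (abs(qi - 1) < 1e-9) {
      exp(-sum(p * log(p)))
    } else {
      sum(p^qi)^(1 / (1 - qi))
    }
  }, numeric(1))
}

check_q <- function(q) {
  if (length(q) != 1L || !is.numeric(q) || !is.finite(q) || q < 0) {
    stop_gsimpson("`q` must be a single number >= 0.",
                  class = "gsimpson_domain_error")
  }
  q
}

#' HCDT order matching a generalized Simpson order
#'
#' Finds the HCDT order `q` whose Hill diversity equals the generalized
#' Simpson effective number at order `r`, i.e. solves
#' \eqn{{}^{q}D^{T} = {}^{r}D^{\zeta}}. Because
#' \eqn{{}^{2}T = \zeta_1} implies \eqn{{}^{2}D^{T} = 1/(1 - \zeta_1)
#' = {}^{1}D^{\zeta}}, the solution at \eqn{r = 1} is exactly
#' \eqn{q = 2}. Solved by root bracketing on \eqn{q \in [0, 2]}, expanding
#' the upper end as needed; \eqn{{}^{q}D^{T}} is strictly decreasing in `q`
#' for non-uniform communities so the root is unique.
#'
#' @inheritParams hcdt_entropy
#' @param r Generalized Simpson order, integer >= 1.
#' @return The matching HCDT order `q`.
#' @export
match_q <- function(x, r) {
  comm <- as_community(x)
  p <- comm$prob
  r <- check_order(r)
  if (is_uniform(p)) {
    stop_gsimpson("`match_q` is degenerate for a uniform community: every q gives diversity S.",
                  class = "gsimpson_degenerate_error")
  }
  target <- effective_number(zeta(comm, r), r)
  g <- function(q) hill_diversity(comm, q) - target
  lo <- 0
  hi <- 2
  if (g(lo) < 0) {
    stop_gsimpson(
      "no HCDT order q >= 0 matches: the generalized Simpson effective number exceeds the richness S.",
      class = "gsimpson_domain_error"
    )
  }
  while (g(hi) > 0 && hi < 1024) hi <- hi * 2
  if (g(hi) > 0) {
    stop_gsimpson("failed to bracket the matching q.", class = "gsimpson_domain_error")
  }
  uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' Hurlbert's diversity index
#'
#' \deqn{{}^{k}H = \sum_s \left[1 - (1 - p_s)^k\right]:}
#' the expected number of species found in a random sample of `k`
#' individuals. \eqn{{}^{1}H = 1}, \eqn{{}^{2}H = 1 + \zeta_1}, and
#' \eqn{{}^{k}H} increases with `k` toward the richness `S`. Larger `k`
#' gives more weight to rare species.
#'
#' @inheritParams hcdt_entropy
#' @param k Sample size parameter, integer >= 1.
#' @return Expected species count(s) in \[1, min(k, S)\].
#' @export
hurlbert_index <- function(x, k) {
  p <- community_probs(x)
  vapply(k, function(ki) {
    ki <- check_order(ki, what = "`k`")
    sum(1 - (1 - p)^ki)
  }, numeric(1))
}

#' Unbiased estimator of Hurlbert's index
#'
#' The rarefaction estimator
#' \deqn{\hat H_k = \sum_{s=1}^{K}\left[1 -
#'   \binom{n - n'_s}{k} \Big/ \binom{n}{k}\right]}
#' is unbiased for \eqn{{}^{k}H} for every \eqn{k < n} (and at \eqn{k = n}
#' returns the observed richness `K`). Binomial coefficients are evaluated
#' through [lchoose()] so samples of any realistic size are handled without
#' overflow. The identity \eqn{\hat H_2 = 1 + Z_1} ties this estimator to
#' the unbiased generalized Simpson estimator.
#'
#' @param x An [abundances] sample.
#' @param k Subsample size(s), integer with \eqn{1 \le k \le n}.
#' @return Unbiased estimate(s) of the expected species count.
#' @export
hurlbert_estimate <- function(x, k) {
  smp <- as_abundances(x)
  n <- sum(smp$count)
  vapply(k, function(ki) {
    ki <- check_order(ki, upper = n, what = "`k`")
    # lchoose(m, k) = -Inf when k > m, so impossible subsamples contribute 1
    sum(1 - exp(lchoose(n - smp$count, ki) - lchoose(n, ki)))
  }, numeric(1))
}

#' Effective number of species for Hurlbert's index
#'
#' The number `D` of equally frequent species for which a sample of `k`
#' individuals is expected to contain `value` species, i.e. the root of
#' \deqn{D\left[1 - (1 - 1/D)^k\right] = {}^{k}H.}
#' The left side is strictly increasing in `D` from 1 (at `D = 1`) to `k`
#' (as \eqn{D \to \infty}), so the root is unique; it is found by monotone
#' bracketing to a tolerance of 1e-9. A value equal to `k` maps to `Inf`.
#'
#' @param value Index value in \[1, k\].
#' @param k Sample size parameter, integer >= 1.
#' @return Effective number of species >= 1 (possibly `Inf`).
#' @export
hurlbert_effective_number <- function(value, k) {
  k <- check_order(k, what = "`k`")
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value < 1 || value > k) {
    stop_gsimpson("`value` must lie in [1, k].", class = "gsimpson_domain_error")
  }
  if (value == 1) return(1)
  if (k == 1 || value >= k) return(Inf)
  g <- function(D) D * (1 - (1 - 1 / D)^k) - value
  hi <- 2
  while (g(hi) < 0 && hi < 1e12) hi <- hi * 2
  uniroot(g, c(1, hi), tol = 1e-9)$root
}

#' Bootstrap percentile interval for a sample statistic
#'
#' Resamples the observed community multinomially (`B` resamples of size
#' `n` from the plug-in proportions) and returns the percentile interval of
#' the statistic. This is the envelope used for indices without an
#' asymptotic variance formula, such as Hurlbert's effective number or
#' plug-in Hill diversities.
#'
#' @param x An [abundances] sample.
#' @param statistic Function mapping an [abundances] object to a single
#'   number.
#' @param B Number of bootstrap resamples (>= 100).
#' @param alpha Envelope level (default 0.05 for a 95\% interval).
#' @param seed Optional integer seed; the same seed reproduces the interval
#'   exactly.
#' @return A tibble with columns `lower`, `upper`, `level`, `B`.
#' @export
bootstrap_envelope <- function(x, statistic, B = 1000, alpha = 0.05, seed = NULL) {
  smp <- as_abundances(x)
  check_alpha(alpha)
  if (B < 100) {
    stop_gsimpson("`B` must be at least 100.", class = "gsimpson_domain_error")
  }
  n <- sum(smp$count)
  phat <- smp$count / n
  if (!is.null(seed)) set.seed(seed)
  draws <- rmultinom(B, n, phat)
  stats <- apply(draws, 2L, function(cnt) {
    statistic(abundances(cnt[cnt > 0], labels = smp$species[cnt > 0]))
  })
  qs <- quantile(stats, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  tibble::tibble(lower = qs[1], upper = qs[2], level = 1 - alpha, B = as.integer(B))
}
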