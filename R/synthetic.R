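#' Build a synthetic community from a standard abundance model
#'
#' Deterministic species-abundance distributions used throughout the test
#' and simulation machinery:
#' \describe{
#'   \item{uniform}{\eqn{p_s = 1/S}.}
#'   \item{geometric}{\eqn{p_s \propto \rho^{s-1}} with ratio
#'     \eqn{0 < \rho \le 1}; the classic niche-preemption series.}
#'   \item{log_series}{\eqn{p_s \propto \theta^s / s} with
#'     \eqn{0 < \theta < 1} (Fisher's log-series shape, truncated at S).}
#'   \item{zipf}{\eqn{p_s \propto s^{-\gamma}} with exponent
#'     \eqn{\gamma > 0}.}
#' }
#' All models are normalized over the `S` species, so the result is a valid
#' [community].
#'
#' @param family One of `"uniform"`, `"geometric"`, `"log_series"`,
#'   `"zipf"`.
#' @param S Number of species, >= 1.
#' @param param Shape parameter (ratio, theta, or exponent); ignored for
#'   `"uniform"`.
#' @return A [community] of `S` species.
#' @examples
#' make_community("geometric", S = 3, param = 0.5) # probs 4/7, 2/7, 1/7
#' @export
make_community <- function(family = c("uniform", "geometric", "log_series", "zipf"),
                           S, param = NULL) {
  family <- match.arg(family)
  if (length(S) != 1L || S < 1 || S != floor(S)) {
    stop_gsimpson("`S` must be a single integer >= 1.",
                  class = "gsimpson_domain_error")
  }
  s <- seq_len(S)
  w <- switch(family,
    uniform = rep(1, S),
    geometric = {
      check_param(param, "ratio", lower = 0, upper = 1, upper_closed = TRUE)
      param^(s - 1)
    },
    log_series = {
      check_param(param, "theta", lower = 0, upper = 1)
      param^s / s
    },
    zipf = {
      check_param(param, "exponent", lower = 0, upper = Inf)
      s^(-param)
    }
  )
  community(w / sum(w))
}

check_param <- function(param, name, lower, upper, upper_closed = FALSE) {
  ok <- is.numeric(param) && length(param) == 1L && is.finite(param) &&
    param > lower && (if (upper_closed) param <= upper else param < upper)
  if (!ok) {
    stop_gsimpson(
      sprintf("`param` (%s) must lie in (%s, %s%s.", name, format(lower),
              format(upper), if (upper_closed) "]" else ")"),
      class = "gsimpson_domain_error"
    )
  }
  invisible(param)
}

#' Draw a multinomial sample from a community
#'
#' Samples `n` individuals independently with replacement (equivalently,
#' from an effectively infinite population) and returns the observed
#' abundance table. Species not drawn are omitted, matching the convention
#' that a sample records only the `K` observed species.
#'
#' @param x A [community].
#' @param n Sample size, integer >= 1.
#' @param seed Optional integer seed; the same seed and arguments reproduce
#'   the sample exactly.
#' @return An [abundances] sample.
#' @export
sample_community <- function(x, n, seed = NULL) {
  comm <- as_community(x)
  if (length(n) != 1L || n < 1 || n != floor(n)) {
    stop_gsimpson("`n` must be a single integer >= 1.",
                  class = "gsimpson_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  cnt <- as.integer(rmultinom(1L, n, comm$prob)[, 1L])
  keep <- cnt > 0L
  abundances(cnt[keep], labels = comm$species[keep])
}

#' Exact expectation of a sample statistic by multinomial enumeration
#'
#' Enumerates every possible outcome of a multinomial sample of size `n`
#' from the community (all compositions of `n` into `S` parts), weights
#' each by its multinomial probability (computed in log space), and sums
#' `statistic(outcome)`. This is the independent oracle for exactness
#' claims: unbiasedness of the generalized Simpson estimator
#' (\eqn{E[Z_r] = \zeta_r}) and of Hurlbert's rarefaction estimator, and
#' the negative bias of plug-in estimators. Refuses problems beyond
#' \eqn{S \le 4, n \le 8}, where enumeration stops being exact-and-instant.
#'
#' @param x A [community] with at most 4 species.
#' @param n Sample size, at most 8.
#' @param statistic Function mapping an [abundances] object (observed
#'   species only) to a single number.
#' @return The exact expectation, to floating-point precision.
#' @examples
#' comm <- community(c(2 / 3, 1 / 3))
#' enumerate_expectation(comm, 3, function(s) zeta_estimate(s, 1)) # = zeta_1 = 4/9
#' @export
enumerate_expectation <- function(x, n, statistic) {
  comm <- as_community(x)
  S <- nrow(comm)
  if (S > 4 || n > 8) {
    stop_gsimpson("enumeration is limited to S <= 4 and n <= 8.",
                  class = "gsimpson_domain_error")
  }
  if (length(n) != 1L || n < 1 || n != floor(n)) {
    stop_gsimpson("`n` must be a single integer >= 1.",
                  class = "gsimpson_domain_error")
  }
  p <- comm$prob
  logp <- log(p)
  total <- 0
  for (cnt in compositions(n, S)) {
    logprob <- lgamma(n + 1) - sum(lgamma(cnt + 1)) + sum(cnt * logp)
    keep <- cnt > 0L
    smp <- abundances(cnt[keep], labels = comm$species[keep])
    total <- total + exp(logprob) * statistic(smp)
  }
  total
}

# all compositions of n into S non-negative parts, as a list
compositions <- function(n, S) {
  if (S == 1L) return(list(n))
  out <- list()
  for (first in 0:n) {
    for (rest in compositions(n - first, S - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

#' Empirical coverage of the entropy confidence interval
#'
#' Repeatedly samples from a known community, builds the asymptotic
#' \eqn{(1-\alpha)} confidence interval for \eqn{\zeta_r} at each
#' replicate, and returns the fraction of replicates whose interval covers
#' the true value. For a non-uniform community and moderate `n` this should
#' sit near \eqn{1 - \alpha}; a uniform community is refused because its
#' asymptotic distribution is degenerate.
#'
#' @param x A non-uniform [community].
#' @param n Per-replicate sample size.
#' @param r Order of the entropy.
#' @param reps Number of replicates (>= 100).
#' @param alpha Interval level (default 0.05).
#' @param seed Optional integer seed for the single stream driving all
#'   replicates.
#' @return Empirical coverage in \[0, 1\].
#' @export
coverage_experiment <- function(x, n, r, reps, alpha = 0.05, seed = NULL) {
  comm <- as_community(x)
  # alpha = 1 is allowed here (zero-width intervals, coverage ~ 0): useful
  # as a sanity extreme in simulation studies
  if (length(alpha) != 1L || !is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop_gsimpson("`alpha` must be a single number in (0, 1].",
                  class = "gsimpson_domain_error")
  }
  if (is_uniform(comm$prob)) {
    stop_gsimpson("coverage is undefined for a uniform community (degenerate asymptotics).",
                  class = "gsimpson_degenerate_error")
  }
  if (reps < 100) {
    stop_gsimpson("`reps` must be at least 100.", class = "gsimpson_domain_error")
  }
  r <- check_order(r, upper = n - 1)
  truth <- zeta(comm, r)
  z <- qnorm(1 - alpha / 2)
  if (!is.null(seed)) set.seed(seed)
  draws <- rmultinom(reps, n, comm$prob)
  covered <- apply(draws, 2L, function(cnt) {
    cnt <- cnt[cnt > 0L]
    est <- z_estimate_all(cnt, n, r)[r]
    sig <- if (length(cnt) < 2L || is_uniform(cnt / n)) 0 else zeta_sigma(cnt / n, r)
    half <- z * sig / sqrt(n)
    max(est - half, 0) <= truth && truth <= min(est + half, 1)
  })
  mean(covered)
}
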