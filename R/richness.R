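#' Frequency counts of a sample
#'
#' \eqn{f_i}: the number of species observed exactly `i` times. These are
#' the sufficient statistics of the jackknife richness family (singletons
#' \eqn{f_1}, doubletons \eqn{f_2}, ...).
#'
#' @param x An [abundances] sample.
#' @param max_i Largest multiplicity to tabulate.
#' @return Integer vector `f` of length `max_i` with `f[i]` the number of
#'   species of count `i`.
#' @examples
#' frequency_counts(c(1, 1, 2, 3), 3) # 2, 1, 1
#' @export
frequency_counts <- function(x, max_i) {
  smp <- as_abundances(x)
  if (length(max_i) != 1L || max_i < 1 || max_i != floor(max_i)) {
    stop_gsimpson("`max_i` must be a single integer >= 1.",
                  class = "gsimpson_domain_error")
  }
  vapply(seq_len(max_i), function(i) sum(smp$count == i), integer(1))
}

# Burnham-Overton jackknife coefficients: order-k estimate is
# K + sum_i coef[i] * f_i, i = 1..k.
jackknife_coefficients <- function(k, n) {
  switch(k,
    # k = 1
    (n - 1) / n,
    # k = 2
    c((2 * n - 3) / n,
      -(n - 2)^2 / (n * (n - 1))),
    # k = 3
    c((3 * n - 6) / n,
      -(3 * n^2 - 15 * n + 19) / (n * (n - 1)),
      (n - 3)^3 / (n * (n - 1) * (n - 2))),
    # k = 4
    c((4 * n - 10) / n,
      -(6 * n^2 - 36 * n + 55) / (n * (n - 1)),
      (4 * n^3 - 42 * n^2 + 148 * n - 175) / (n * (n - 1) * (n - 2)),
      -(n - 4)^4 / (n * (n - 1) * (n - 2) * (n - 3))),
    # k = 5
    c((5 * n - 15) / n,
      -(10 * n^2 - 70 * n + 125) / (n * (n - 1)),
      (10 * n^3 - 120 * n^2 + 485 * n - 660) / (n * (n - 1) * (n - 2)),
      -((n - 4)^5 - (n - 5)^5) / (n * (n - 1) * (n - 2) * (n - 3)),
      (n - 5)^5 / (n * (n - 1) * (n - 2) * (n - 3) * (n - 4)))
  )
}

jackknife_point <- function(K, f, k, n) {
  coef <- jackknife_coefficients(k, n)
  K + sum(coef * f[seq_len(k)])
}

#' Jackknife estimate of species richness
#'
#' The order-`k` jackknife corrects the observed richness `K` for unseen
#' species using the frequency counts \eqn{f_1, \dots, f_k} (Burnham &
#' Overton family, orders 1-5), e.g. order 1:
#' \eqn{\hat S_1 = K + f_1 (n-1)/n}; order 2:
#' \eqn{\hat S_2 = K + f_1 (2n-3)/n - f_2 (n-2)^2 / (n(n-1))}. Higher
#' orders remove higher-order bias terms at the price of variance.
#'
#' When `order = NULL` the order is chosen by the sequential significance
#' test of [select_jackknife_order()]. The main use of the estimate here is
#' to bound the diversity profile: generalized Simpson's entropy is a valid
#' diversity measure only for \eqn{r \le S - 1}, so profiles run to
#' \eqn{\hat S - 1} (see [max_valid_order()]).
#'
#' @param x An [abundances] sample.
#' @param order Jackknife order 1-5, or `NULL` for automatic selection.
#' @return A `richness_estimate`: list with `estimate`, `order`, `K`, `n`,
#'   and the frequency counts `f` (length `order + 1`).
#' @examples
#' jackknife_richness(c(1, 1, 1, 3, 4), order = 1) # 5 + 3 * 9/10 = 7.7
#' @export
jackknife_richness <- function(x, order = NULL) {
  smp <- as_abundances(x)
  n <- sum(smp$count)
  K <- nrow(smp)
  if (is.null(order)) {
    order <- select_jackknife_order(smp)
  }
  if (length(order) != 1L || order < 1 || order > 5 || order != floor(order)) {
    stop_gsimpson("`order` must be an integer between 1 and 5.",
                  class = "gsimpson_domain_error")
  }
  order <- as.integer(order)
  if (n <= order) {
    stop_gsimpson("the sample size must exceed the jackknife order.",
                  class = "gsimpson_domain_error")
  }
  f <- frequency_counts(smp, min(order + 1L, n))
  est <- jackknife_point(K, f, order, n)
  out <- list(estimate = est, order = order, K = K, n = n, f = f)
  class(out) <- "richness_estimate"
  out
}

#' Select the jackknife order by sequential testing
#'
#' Burnham-Overton sequential procedure: for \eqn{k = 1, 2, \dots} test
#' whether the order-\eqn{(k+1)} estimate differs significantly from the
#' order-\eqn{k} estimate, using the conditional variance
#' \deqn{\widehat{\mathrm{Var}}(\hat S_{k+1} - \hat S_k) =
#'   \frac{n}{n-1}\left(\sum_i d_i^2 f_i -
#'   \frac{(\hat S_{k+1} - \hat S_k)^2}{n}\right),}
#' where \eqn{d_i} is the difference of the coefficients multiplying
#' \eqn{f_i} in the two estimates. The selected order is the smallest `k`
#' whose test is non-significant at `alpha` (the increment from going one
#' order higher is indistinguishable from noise), capped at order 5.
#'
#' A sample with no singletons gives order 1 immediately (nothing indicates
#' unseen species). Degenerate samples (K < 2) return order 1 with a
#' warning.
#'
#' @param x An [abundances] sample.
#' @param alpha Test level (default 0.05).
#' @return Integer order in 1..5.
#' @export
select_jackknife_order <- function(x, alpha = 0.05) {
  smp <- as_abundances(x)
  check_alpha(alpha)
  n <- sum(smp$count)
  K <- nrow(smp)
  if (K < 2L || n <= 2L) {
    warn_gsimpson("degenerate sample: defaulting to jackknife order 1.",
                  class = "gsimpson_degenerate_warning")
    return(1L)
  }
  f <- frequency_counts(smp, min(6L, n))
  if (f[1] == 0L) return(1L)
  zcrit <- qnorm(1 - alpha / 2)
  kmax <- min(5L, n - 1L, length(f))
  for (k in seq_len(kmax - 1L)) {
    ck <- jackknife_coefficients(k, n)
    ck1 <- jackknife_coefficients(k + 1L, n)
    d <- ck1 - c(ck, 0)
    fk <- f[seq_len(k + 1L)]
    diff <- sum(d * fk)
    v <- (n / (n - 1)) * (sum(d^2 * fk) - diff^2 / n)
    if (v <= 0 || abs(diff) / sqrt(v) <= zcrit) return(k)
  }
  kmax
}

#' Maximal valid profile order implied by a richness estimate
#'
#' Generalized Simpson's entropy respects the evenness axiom only for
#' \eqn{r \le S - 1}; profiles therefore run to
#' \eqn{\lfloor \hat S \rfloor - 1}. Flooring a fractional estimate is the
#' conservative choice (never exceeding the estimated \eqn{S - 1}).
#'
#' @param richness A [jackknife_richness()] result, or a plain number
#'   \eqn{\hat S \ge 2}.
#' @return Integer \eqn{\lfloor \hat S \rfloor - 1}.
#' @examples
#' max_valid_order(254) # 253
#' @export
max_valid_order <- function(richness) {
  est <- if (inherits(richness, "richness_estimate")) richness$estimate else richness
  if (!is.numeric(est) || length(est) != 1L || est < 2) {
    stop_gsimpson("the richness estimate must be a single number >= 2.",
                  class = "gsimpson_domain_error")
  }
  as.integer(floor(est)) - 1L
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("Jackknife richness estimate (order %d): %.2f species\n", x$order, x$estimate))
  cat(sprintf("  observed: K = %d species in n = %d individuals; f = (%s)\n",
              x$K, x$n, paste(x$f, collapse = ", ")))
  invisible(x)
}
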