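#' Generalized Simpson's entropy of a known community
#'
#' \deqn{\zeta_r = \sum_{s=1}^{S} p_s (1 - p_s)^r}
#'
#' \eqn{\zeta_r} is the probability that the \eqn{(r+1)}st individual drawn
#' from the community belongs to a species not seen among the first \eqn{r}
#' draws, i.e. the slope of the species accumulation curve at rank
#' \eqn{r + 1}. \eqn{1 - \zeta_1} is Simpson's index \eqn{\sum_s p_s^2}.
#' Larger orders `r` weight rare species more heavily; \eqn{\zeta_r}
#' respects the evenness axiom (maximal at the uniform community) only for
#' \eqn{r \le S - 1}, which is the range in which it should be read as a
#' diversity measure.
#'
#' @param x A [community], proportion vector, or anything
#'   [as_community()] accepts.
#' @param r Order(s) of the entropy: integer(s) >= 1. Vectorized.
#' @return Numeric vector of \eqn{\zeta_r} values in \[0, 1\], one per order.
#' @examples
#' zeta(c(0.5, 0.3, 0.2), r = 2) # 0.4
#' zeta(rep(0.1, 10), r = 3)     # (1 - 1/10)^3 = 0.729
#' @export
zeta <- function(x, r) {
  p <- community_probs(x)
  vapply(r, function(ri) {
    ri <- check_order(ri)
    sum(p * (1 - p)^ri)
  }, numeric(1))
}

#' Information function of generalized Simpson's entropy
#'
#' \eqn{I(p) = (1 - p)^r}: the probability of not seeing a single
#' individual of a species with proportion `p` in a sample of size `r` — an
#' intuitive measure of the rarity of that species. It is strictly
#' decreasing in `p` with \eqn{I(1) = 0}, so \eqn{\zeta_r = \sum_s p_s
#' I(p_s)} is a trace-form (dichotomous) diversity index.
#'
#' @param p Proportion(s) in (0, 1].
#' @param r Order, integer >= 1.
#' @return \eqn{(1 - p)^r}.
#' @export
zeta_information <- function(p, r) {
  r <- check_order(r)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_gsimpson("`p` must lie in (0, 1].", class = "gsimpson_domain_error")
  }
  (1 - p)^r
}

#' Effective number of species for generalized Simpson's entropy
#'
#' Inverts \eqn{\zeta_r = (1 - 1/D)^r} to give the number of equally
#' frequent species that would produce the same entropy:
#' \deqn{{}^{r}D^{\zeta} = \frac{1}{1 - \zeta_r^{1/r}}.}
#' The transform is monotone increasing, so confidence limits for
#' \eqn{\zeta_r} map directly to confidence limits for the effective
#' number, and inference on either scale is equivalent.
#'
#' A value of exactly 1 (possible for an upper confidence limit clamped at
#' 1, or for an all-singleton sample) maps to `Inf` rather than raising an
#' error: the data are consistent with unbounded diversity.
#'
#' @param zeta_value Entropy value(s) in \[0, 1\].
#' @param r Order, integer >= 1.
#' @return Effective number(s) of species, >= 1 (possibly `Inf`).
#' @examples
#' effective_number(0.5, r = 1) # 2 equiprobable species
#' effective_number(zeta(rep(1 / 20, 20), 3), 3) # 20
#' @export
effective_number <- function(zeta_value, r) {
  r <- check_order(r)
  if (!is.numeric(zeta_value) || any(!is.finite(zeta_value) & !is.nan(zeta_value)) ||
      any(zeta_value < 0)) {
    stop_gsimpson("`zeta_value` must be numeric in [0, 1].",
                  class = "gsimpson_domain_error")
  }
  if (any(zeta_value > 1 + 1e-12)) {
    stop_gsimpson("`zeta_value` must not exceed 1.", class = "gsimpson_domain_error")
  }
  zeta_value <- pmin(zeta_value, 1)
  ifelse(zeta_value >= 1, Inf, 1 / (1 - zeta_value^(1 / r)))
}

#' Transfer of probability between two species
#'
#' Moves probability mass `h` from a more abundant species `t` to a less
#' abundant species `s` without changing their order (`p_s + h <= p_t - h`
#' must hold). Under the weak principle of transfers, any such transfer
#' increases \eqn{\zeta_r} provided \eqn{p_s + p_t \le 2/(r+1)} (see
#' [transfer_threshold()]).
#'
#' @param x A [community].
#' @param s,t Indices of the recipient (rarer) and donor (more abundant)
#'   species; `p_s < p_t` required.
#' @param h Amount of probability transferred, > 0.
#' @return A new `community` with the transfer applied.
#' @export
apply_transfer <- function(x, s, t, h) {
  comm <- as_community(x)
  p <- comm$prob
  S <- length(p)
  if (s < 1 || s > S || t < 1 || t > S || s == t) {
    stop_gsimpson("`s` and `t` must be distinct species indices.",
                  class = "gsimpson_invalid_transfer")
  }
  if (!(p[s] < p[t])) {
    stop_gsimpson("a transfer requires p_s < p_t.",
                  class = "gsimpson_invalid_transfer")
  }
  if (!is.numeric(h) || length(h) != 1L || h <= 0 || p[s] + h > p[t] - h + 1e-15) {
    stop_gsimpson("`h` must satisfy 0 < h and p_s + h <= p_t - h (order-preserving).",
                  class = "gsimpson_invalid_transfer")
  }
  p[s] <- p[s] + h
  p[t] <- p[t] - h
  community(p, labels = comm$species)
}

#' Threshold of the weak principle of transfers
#'
#' \eqn{\zeta_r} satisfies the full principle of transfers only for
#' \eqn{r = 1} (the Simpson case). For general `r` it satisfies the weak
#' principle: any order-preserving transfer between species `s` and `t`
#' with \eqn{p_s + p_t \le T} increases the index, where
#' \deqn{T = \frac{2}{r + 1}.}
#'
#' @param r Order, integer >= 1.
#' @return The threshold \eqn{2 / (r + 1)}.
#' @examples
#' transfer_threshold(1) # 1: every transfer increases zeta_1
#' transfer_threshold(3) # 0.5
#' @export
transfer_threshold <- function(r) {
  r <- check_order(r)
  2 / (r + 1)
}
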