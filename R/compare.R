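#' Confidence interval for the difference in entropy between two communities
#'
#' For independent samples from two communities, an asymptotic
#' \eqn{(1-\alpha)} confidence interval for
#' \eqn{\zeta_r^{(1)} - \zeta_r^{(2)}} is
#' \deqn{\left(Z_r^{(1)} - Z_r^{(2)}\right) \pm z_{\alpha/2}
#'   \sqrt{\hat\sigma_{r,1}^2 / n_1 + \hat\sigma_{r,2}^2 / n_2}.}
#' The interval is not clamped: a difference of probabilities lives in
#' \[-1, 1\]. A degenerate sample (exactly uniform observed proportions)
#' contributes zero variance, with a warning.
#'
#' @param x,y Two independent [abundances] samples (or anything
#'   [as_abundances()] accepts).
#' @param r Order(s); must satisfy \eqn{r \le \min(n_1, n_2) - 1}.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with columns `order`, `difference`, `se`, `lower`,
#'   `upper`, `level`.
#' @export
zeta_difference <- function(x, y, r, alpha = 0.05) {
  a <- as_abundances(x)
  b <- as_abundances(y)
  check_alpha(alpha)
  n1 <- sum(a$count)
  n2 <- sum(b$count)
  for (ri in r) check_order(ri, upper = min(n1, n2) - 1)
  z <- qnorm(1 - alpha / 2)
  d <- zeta_estimate(a, r) - zeta_estimate(b, r)
  se <- sqrt(zeta_se(a, r)^2 / n1 + zeta_se(b, r)^2 / n2)
  tibble::tibble(
    order = as.integer(r),
    difference = d,
    se = se,
    lower = d - z * se,
    upper = d + z * se,
    level = 1 - alpha
  )
}

#' Difference profile between two communities
#'
#' Assembles [zeta_difference()] intervals for every order
#' \eqn{r = 1, \dots, v} into a pointwise confidence envelope for the
#' entropy difference. Equal diversity at order `r` is rejected (pointwise)
#' when 0 lies outside the interval at that order; see
#' [significance_summary()] for the overall reading.
#'
#' @inheritParams zeta_difference
#' @param max_order Largest order `v`, \eqn{v \le \min(n_1, n_2) - 1}.
#' @param richness Optional richness estimate bounding the valid range
#'   (orders above \eqn{\hat S - 1} are flagged, as in [zeta_profile()]).
#' @return A `zeta_difference_profile` tibble with columns `order`,
#'   `difference`, `se`, `lower`, `upper`, `level`, `contains_zero`.
#' @export
zeta_difference_profile <- function(x, y, max_order, alpha = 0.05,
                                    richness = NULL) {
  a <- as_abundances(x)
  b <- as_abundances(y)
  check_alpha(alpha)
  n1 <- sum(a$count)
  n2 <- sum(b$count)
  v <- check_order(max_order, upper = min(n1, n2) - 1, what = "`max_order`")
  z <- qnorm(1 - alpha / 2)

  d <- z_estimate_all(a$count, n1, v) - z_estimate_all(b$count, n2, v)
  s1 <- suppress_degenerate(zeta_se(a, seq_len(v)))
  s2 <- suppress_degenerate(zeta_se(b, seq_len(v)))
  se <- sqrt(s1^2 / n1 + s2^2 / n2)

  prof <- tibble::tibble(
    order = seq_len(v),
    difference = d,
    se = se,
    lower = d - z * se,
    upper = d + z * se,
    level = 1 - alpha
  )
  prof$contains_zero <- prof$lower <= 0 & prof$upper >= 0
  if (!is.null(richness)) {
    bound <- max_valid_order(richness)
    prof$valid <- prof$order <= bound
    if (any(!prof$valid)) {
      warn_gsimpson(
        sprintf("orders beyond r = %d exceed the estimated richness bound.", bound),
        class = "gsimpson_order_warning"
      )
    }
  }
  attr(prof, "n1") <- n1
  attr(prof, "n2") <- n2
  attr(prof, "alpha") <- alpha
  class(prof) <- c("zeta_difference_profile", class(prof))
  prof
}

#' Significance summary of a difference profile
#'
#' Operationalizes the envelope reading of a two-community comparison:
#' equal diversity is rejected overall when zero lies outside the
#' confidence interval at *every* order ("significant"), not rejected when
#' zero lies inside at every order ("not significant"), and the comparison
#' is "inconclusive" otherwise. The envelope is pointwise, with no
#' multiplicity correction — the per-order decisions are each at the stated
#' level, and the overall verdict is a descriptive convention, not a
#' family-wise test.
#'
#' @param profile A [zeta_difference_profile()] result.
#' @return A `zeta_significance` object: list with `verdict` (one of
#'   `"significant"`, `"not_significant"`, `"inconclusive"`), `per_order`
#'   (tibble of order and `contains_zero`), `level`, and
#'   `pointwise = TRUE`.
#' @export
significance_summary <- function(profile) {
  if (!inherits(profile, "zeta_difference_profile") || nrow(profile) == 0L) {
    stop_gsimpson("`profile` must be a non-empty zeta_difference_profile.",
                  class = "gsimpson_domain_error")
  }
  inside <- profile$contains_zero
  verdict <- if (all(!inside)) {
    "significant"
  } else if (all(inside)) {
    "not_significant"
  } else {
    "inconclusive"
  }
  out <- list(
    verdict = verdict,
    per_order = tibble::tibble(order = profile$order, contains_zero = inside),
    level = profile$level[1],
    pointwise = TRUE
  )
  class(out) <- "zeta_significance"
  out
}

#' @export
print.zeta_significance <- function(x, ...) {
  txt <- switch(x$verdict,
    significant = sprintf(
      "significant at every order: zero is outside the %g%% pointwise envelope at all %d orders; identical diversity is rejected.",
      100 * x$level, nrow(x$per_order)),
    not_significant = sprintf(
      "no significant difference: zero is inside the %g%% pointwise envelope at all %d orders.",
      100 * x$level, nrow(x$per_order)),
    inconclusive = sprintf(
      "inconclusive: zero is outside the %g%% pointwise envelope at %d of %d orders.",
      100 * x$level, sum(!x$per_order$contains_zero), nrow(x$per_order))
  )
  cat(txt, "\n")
  invisible(x)
}

#' @export
print.zeta_difference_profile <- function(x, ...) {
  cat(sprintf("<zeta difference profile: orders 1..%d, n1 = %d, n2 = %d, %g%% pointwise envelope>\n",
              max(x$order), attr(x, "n1"), attr(x, "n2"), 100 * x$level[1]))
  NextMethod()
  invisible(x)
}
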