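#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an entropy/diversity profile
#'
#' @param x A [zeta_profile()] result.
#' @param ... Unused.
#' @return A plain tibble, one row per order.
#' @method tidy zeta_profile
#' @export
tidy.zeta_profile <- function(x, ...) {
  tibble::as_tibble(unclass_profile(x))
}

#' @method tidy zeta_difference_profile
#' @export
tidy.zeta_difference_profile <- function(x, ...) {
  tibble::as_tibble(unclass_profile(x))
}

unclass_profile <- function(x) {
  cls <- class(x)
  class(x) <- setdiff(cls, c("zeta_profile", "zeta_difference_profile"))
  x
}

#' One-row summary of a profile
#'
#' @param x A [zeta_profile()] result.
#' @param ... Unused.
#' @return A one-row tibble with the sample size, observed richness,
#'   largest order, scale, and envelope level.
#' @method glance zeta_profile
#' @export
glance.zeta_profile <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"),
    K = attr(x, "K"),
    max_order = max(x$order),
    scale = x$scale[1],
    level = x$level[1]
  )
}

#' @method glance zeta_difference_profile
#' @export
glance.zeta_difference_profile <- function(x, ...) {
  tibble::tibble(
    n1 = attr(x, "n1"),
    n2 = attr(x, "n2"),
    max_order = max(x$order),
    level = x$level[1],
    orders_excluding_zero = sum(!x$contains_zero),
    verdict = significance_summary(x)$verdict
  )
}

#' Tidy a jackknife richness estimate
#'
#' @param x A [jackknife_richness()] result.
#' @param ... Unused.
#' @return A tibble with one row per frequency count plus the estimate
#'   metadata in [glance.richness_estimate()].
#' @method tidy richness_estimate
#' @export
tidy.richness_estimate <- function(x, ...) {
  tibble::tibble(multiplicity = seq_along(x$f), f = x$f)
}

#' @method glance richness_estimate
#' @export
glance.richness_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, order = x$order, K = x$K, n = x$n)
}

#' @method tidy zeta_significance
#' @export
tidy.zeta_significance <- function(x, ...) x$per_order

#' @method glance zeta_significance
#' @export
glance.zeta_significance <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict,
    level = x$level,
    orders = nrow(x$per_order),
    orders_excluding_zero = sum(!x$per_order$contains_zero),
    pointwise = x$pointwise
  )
}
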