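#' Unbiased estimator of generalized Simpson's entropy
#'
#' For a random sample of `n` individuals with observed counts
#' \eqn{n'_1, \dots, n'_K}, the uniformly minimum variance unbiased
#' estimator of \eqn{\zeta_r} (valid for \eqn{1 \le r \le n - 1}) is
#' \deqn{Z_r = \sum_{s=1}^{K} \hat p'_s \prod_{j=1}^{r}
#'   \left(1 - \frac{n'_s - 1}{n - j}\right),}
#' with \eqn{\hat p'_s = n'_s / n}. Every factor lies in \[0, 1\] (a zero
#' factor occurs before any factor could go negative), so the product is
#' accumulated directly, in input order, without log-space tricks, and
#' \eqn{0 \le Z_r \le 1} always.
#'
#' Unlike the plug-in estimator \eqn{\sum_s \hat p_s (1-\hat p_s)^r}, which
#' is biased low, \eqn{E[Z_r] = \zeta_r} exactly under multinomial
#' sampling. No unbiased estimator exists for \eqn{r \ge n}.
#'
#' @param x An [abundances] sample, count vector, or two-column data frame.
#' @param r Order(s), integer(s) with \eqn{1 \le r \le n - 1}. Vectorized.
#' @return Numeric vector of estimates in \[0, 1\].
#' @examples
#' zeta_estimate(c(2, 1), r = 1) # 2/3
#' zeta_estimate(c(2, 2), r = 2) # 1/3
#' @export
zeta_estimate <- function(x, r) {
  smp <- as_abundances(x)
  n <- sum(smp$count)
  vapply(r, function(ri) {
    ri <- check_order(ri, upper = n - 1,
                      what = "order `r` (no unbiased estimator exists beyond n - 1; `r`")
    z_estimate_all(smp$count, n, ri)[ri]
  }, numeric(1))
}

# Z_r for all orders 1..v at once via cumulative products over j.
# counts: observed counts; returns numeric vector of length v.
z_estimate_all <- function(counts, n, v) {
  phat <- counts / n
  # factors[s, j] = 1 - (n'_s - 1)/(n - j); rows cumprod'ed over j
  f <- 1 - outer(counts - 1, n - seq_len(v), "/")
  cp <- row_cumprods(f)
  as.numeric(crossprod(phat, cp))
}

# row-wise cumulative products; preserves matrix shape for v = 1
row_cumprods <- function(m) {
  if (ncol(m) == 1L) return(m)
  t(apply(m, 1L, cumprod))
}

# gradient component e(p) = d/dp [p (1-p)^r] = (1-p)^r - r p (1-p)^(r-1)
zeta_gradient_component <- function(p, r) {
  (1 - p)^r - r * p * (1 - p)^(r - 1)
}

# delta-method sd for a proportion vector (true or estimated).
# Uses the multinomial covariance of the first K-1 proportions:
# sigma^2 = h' Sigma h = sum h_j^2 p_j - (sum h_j p_j)^2, with
# h_j = e(p_j) - e(p_K) (the K-th species eliminated; the quadratic form is
# invariant to which species is eliminated).
zeta_sigma <- function(p, r) {
  K <- length(p)
  e <- zeta_gradient_component(p, r)
  h <- e[-K] - e[K]
  pj <- p[-K]
  v <- sum(h^2 * pj) - sum(h * pj)^2
  sqrt(max(v, 0))
}

#' Asymptotic standard deviation of the entropy estimator
#'
#' Delta-method estimate \eqn{\hat\sigma_r} of the asymptotic standard
#' deviation of \eqn{\sqrt{n}(Z_r - \zeta_r)}, computed as
#' \eqn{\sqrt{\hat h_r^\top \hat\Sigma \hat h_r}} where \eqn{\hat\Sigma} is
#' the multinomial covariance of the first \eqn{K - 1} observed proportions
#' and \eqn{\hat h_r} the gradient of \eqn{\zeta_r} with the last species'
#' proportion eliminated: component
#' \eqn{j} is \eqn{[(1-\hat p_j)^r - r \hat p_j (1-\hat p_j)^{r-1}] -
#' [(1-\hat p_K)^r - r \hat p_K (1-\hat p_K)^{r-1}]}. The quadratic form is
#' invariant to which species plays the eliminated role.
#'
#' When the observed proportions are exactly uniform all gradient
#' components vanish and the asymptotic distribution is degenerate; the
#' function then returns 0 with a warning (so profile construction can
#' continue) rather than erroring. A single-species sample has no free
#' parameter and no defined variance.
#'
#' @inheritParams zeta_estimate
#' @return \eqn{\hat\sigma_r \ge 0} (one value per order).
#' @export
zeta_se <- function(x, r) {
  smp <- as_abundances(x)
  n <- sum(smp$count)
  K <- nrow(smp)
  if (K < 2L) {
    stop_gsimpson("the asymptotic variance is undefined for a single-species sample.",
                  class = "gsimpson_undefined_variance")
  }
  phat <- smp$count / n
  uniform <- is_uniform(phat)
  vapply(r, function(ri) {
    ri <- check_order(ri, upper = n - 1)
    if (uniform) {
      warn_gsimpson(
        "observed proportions are exactly uniform: the asymptotic distribution is degenerate and sigma-hat = 0.",
        class = "gsimpson_degenerate_warning"
      )
      return(0)
    }
    zeta_sigma(phat, ri)
  }, numeric(1))
}

#' Asymptotic standard deviation at known proportions
#'
#' The population (true-p) version of [zeta_se()]: the delta-method
#' standard deviation of \eqn{\sqrt{n}(Z_r - \zeta_r)} evaluated at the
#' known community proportions instead of the observed ones. Used to check
#' the estimator's sampling variability against Monte-Carlo simulation.
#'
#' @param x A [community] with at least 2 species.
#' @param r Order(s), integer >= 1.
#' @return \eqn{\sigma_r \ge 0}, one value per order (0 for a uniform
#'   community, whose asymptotics are degenerate).
#' @export
zeta_asymptotic_sd <- function(x, r) {
  p <- community_probs(x)
  if (length(p) < 2L) {
    stop_gsimpson("the asymptotic variance is undefined for a single-species community.",
                  class = "gsimpson_undefined_variance")
  }
  vapply(r, function(ri) {
    ri <- check_order(ri)
    if (is_uniform(p)) 0 else zeta_sigma(p, ri)
  }, numeric(1))
}

#' Asymptotic confidence interval for generalized Simpson's entropy
#'
#' \deqn{Z_r \pm z_{\alpha/2}\, \hat\sigma_r / \sqrt{n},}
#' clamped to \[0, 1\] since \eqn{\zeta_r} is a probability.
#'
#' @inheritParams zeta_estimate
#' @param alpha Significance level (default 0.05 for a 95\% interval).
#' @return A tibble with columns `order`, `estimate`, `sigma`, `lower`,
#'   `upper`, `level`, `n` — one row per order.
#' @examples
#' zeta_ci(c(12, 5, 3), r = 1)
#' @export
zeta_ci <- function(x, r, alpha = 0.05) {
  smp <- as_abundances(x)
  check_alpha(alpha)
  n <- sum(smp$count)
  z <- qnorm(1 - alpha / 2)
  est <- zeta_estimate(smp, r)
  sig <- zeta_se(smp, r)
  half <- z * sig / sqrt(n)
  tibble::tibble(
    order = as.integer(r),
    estimate = est,
    sigma = sig,
    lower = pmax(est - half, 0),
    upper = pmin(est + half, 1),
    level = 1 - alpha,
    n = n
  )
}

#' Entropy or diversity profile with pointwise confidence envelope
#'
#' Estimates \eqn{\zeta_r} with a \eqn{(1-\alpha)} confidence interval at
#' every order \eqn{r = 1, \dots, v} and assembles the results into a
#' profile. On the `"diversity"` scale, estimate and confidence limits are
#' pushed through the monotone transform [effective_number()], so the
#' envelope is the exact image of the entropy-scale envelope and inference
#' is equivalent on either scale.
#'
#' The envelope is pointwise: each order is covered at the stated level
#' individually, with no simultaneous-coverage adjustment.
#'
#' The statistical validity bound is \eqn{v \le n - 1} (no unbiased
#' estimator beyond it). The diversity-measure bound is \eqn{r \le S - 1};
#' since `S` is unknown, pass a jackknife richness estimate (see
#' [jackknife_richness()]) via `richness` to have orders beyond
#' \eqn{\hat S - 1} flagged (column `valid`) with a warning.
#'
#' @inheritParams zeta_ci
#' @param max_order Largest order `v` (default: chosen automatically as
#'   \eqn{\min(n - 1, \hat S - 1)} using the auto-selected jackknife).
#' @param scale `"entropy"` (probability scale) or `"diversity"`
#'   (effective number of species).
#' @param richness Optional richness estimate (a [jackknife_richness()]
#'   result or a number): orders above \eqn{\lfloor\hat S\rfloor - 1} are
#'   marked invalid.
#' @return A `zeta_profile` tibble with columns `order`, `estimate`,
#'   `sigma`, `lower`, `upper`, `scale`, `level` (plus `valid` when
#'   `richness` is given); attributes `n`, `K`.
#' @examples
#' set.seed(1)
#' smp <- sample_community(make_community("geometric", S = 15, param = 0.7), n = 400)
#' zeta_profile(smp, max_order = 10, scale = "diversity")
#' @export
zeta_profile <- function(x, max_order = NULL, alpha = 0.05,
                         scale = c("entropy", "diversity"), richness = NULL) {
  smp <- as_abundances(x)
  scale <- match.arg(scale)
  check_alpha(alpha)
  n <- sum(smp$count)
  if (is.null(max_order)) {
    rich_auto <- richness %||% jackknife_richness(smp)
    max_order <- min(n - 1L, max_valid_order(rich_auto))
    richness <- richness %||% rich_auto
  }
  v <- check_order(max_order, upper = n - 1, what = "`max_order`")

  est <- z_estimate_all(smp$count, n, v)
  sig <- suppress_degenerate(zeta_se(smp, seq_len(v)))
  z <- qnorm(1 - alpha / 2)
  half <- z * sig / sqrt(n)
  lower <- pmax(est - half, 0)
  upper <- pmin(est + half, 1)

  prof <- tibble::tibble(
    order = seq_len(v),
    estimate = est,
    sigma = sig,
    lower = lower,
    upper = upper,
    scale = scale,
    level = 1 - alpha
  )
  if (scale == "diversity") {
    prof <- dplyr::mutate(
      prof,
      estimate = effective_numbers_by_order(.data$estimate, .data$order),
      lower = effective_numbers_by_order(.data$lower, .data$order),
      upper = effective_numbers_by_order(.data$upper, .data$order)
    )
  }
  if (!is.null(richness)) {
    bound <- max_valid_order(richness)
    prof$valid <- prof$order <= bound
    if (any(!prof$valid)) {
      warn_gsimpson(
        sprintf("orders %d..%d exceed the estimated richness bound r <= %d; zeta_r is not a diversity measure there.",
                bound + 1L, v, bound),
        class = "gsimpson_order_warning"
      )
    }
  }
  attr(prof, "n") <- n
  attr(prof, "K") <- nrow(smp)
  attr(prof, "alpha") <- alpha
  class(prof) <- c("zeta_profile", class(prof))
  prof
}

effective_numbers_by_order <- function(vals, orders) {
  vapply(seq_along(vals), function(i) effective_number(vals[i], orders[i]),
         numeric(1))
}

# run sigma estimation over a whole profile emitting at most one
# degeneracy warning
suppress_degenerate <- function(expr) {
  warned <- FALSE
  out <- withCallingHandlers(expr, gsimpson_degenerate_warning = function(w) {
    if (warned) invokeRestart("muffleWarning") else warned <<- TRUE
  })
  out
}

#' @export
print.zeta_profile <- function(x, ...) {
  cat(sprintf("<zeta profile: %s scale, orders 1..%d, n = %d, K = %d, %g%% pointwise envelope>\n",
              x$scale[1], max(x$order), attr(x, "n"), attr(x, "K"),
              100 * x$level[1]))
  NextMethod()
  invisible(x)
}
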