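#' Plot an entropy or diversity profile
#'
#' Draws the per-order estimates with their pointwise confidence ribbon.
#'
#' @param object A [zeta_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zeta_profile
#' @export
autoplot.zeta_profile <- function(object, ...) {
  ylab <- if (object$scale[1] == "diversity") {
    "effective number of species"
  } else {
    "generalized Simpson's entropy"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$order, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "order r", y = ylab,
      subtitle = sprintf("%g%% pointwise confidence envelope", 100 * object$level[1])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a two-community difference profile
#'
#' Draws the estimated entropy difference per order with its pointwise
#' envelope and the zero line of the identical-diversity hypothesis.
#'
#' @param object A [zeta_difference_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zeta_difference_profile
#' @export
autoplot.zeta_difference_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$order, y = .data$difference)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "order r", y = "entropy difference",
      subtitle = sprintf("%g%% pointwise confidence envelope", 100 * object$level[1])
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.zeta_profile <- function(x, ...) print(autoplot.zeta_profile(x, ...))

#' @export
plot.zeta_difference_profile <- function(x, ...) {
  print(autoplot.zeta_difference_profile(x, ...))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
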