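#' Construct a community from known species proportions
#'
#' A community is the ground-truth object of the package: a vector of
#' species proportions \eqn{p_1, \dots, p_S} with every \eqn{p_s > 0} and
#' \eqn{\sum_s p_s = 1}. All analytic quantities (the generalized Simpson's
#' entropy [zeta()], Hill numbers, Hurlbert's index, ...) are computed from
#' it. Zero proportions are rejected rather than dropped: continuity of the
#' index guarantees that species with \eqn{p \to 0} contribute nothing, so
#' callers can pre-filter without changing any result, and silent dropping
#' would hide data errors. Likewise a proportion vector that does not sum to
#' one (tolerance 1e-12) is refused, never renormalized.
#'
#' @param probs Numeric vector of species proportions; each in (0, 1],
#'   summing to 1 within 1e-12.
#' @param labels Optional character vector of species labels (default
#'   `"sp1" ... "spS"`).
#' @return A `community` object: a tibble with columns `species` and
#'   `prob`, one row per species.
#' @examples
#' community(c(0.5, 0.3, 0.2))
#' @export
community <- function(probs, labels = NULL) {
  if (!is.numeric(probs) || length(probs) < 1L) {
    stop_gsimpson("`probs` must be a non-empty numeric vector.",
                  class = "gsimpson_domain_error")
  }
  if (any(!is.finite(probs)) || any(probs <= 0) || any(probs > 1)) {
    stop_gsimpson(
      "every proportion must satisfy 0 < p <= 1; zero-probability species must be removed by the caller.",
      class = "gsimpson_domain_error"
    )
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop_gsimpson(
      sprintf("proportions must sum to 1 within 1e-12 (got sum = %.15g); renormalization is refused.",
              sum(probs)),
      class = "gsimpson_domain_error"
    )
  }
  if (is.null(labels)) {
    labels <- paste0("sp", seq_along(probs))
  } else {
    labels <- as.character(labels)
    if (length(labels) != length(probs) || anyDuplicated(labels)) {
      stop_gsimpson("`labels` must be unique and match `probs` in length.",
                    class = "gsimpson_domain_error")
    }
  }
  out <- tibble::tibble(species = labels, prob = as.numeric(probs))
  class(out) <- c("community", class(out))
  out
}

#' Coerce to a community
#'
#' @param x A `community`, a numeric vector of proportions, a two-column
#'   data frame (species, proportion), or an [abundances] object (whose
#'   plug-in proportions \eqn{\hat p_s = n_s / n} are used).
#' @param ... Unused.
#' @return A `community`.
#' @export
as_community <- function(x, ...) UseMethod("as_community")

#' @export
as_community.community <- function(x, ...) x

#' @export
as_community.numeric <- function(x, ...) community(x, labels = names(x))

#' @export
as_community.abundances <- function(x, ...) {
  community(x$count / sum(x$count), labels = x$species)
}

#' @export
as_community.data.frame <- function(x, ...) {
  if (inherits(x, "abundances")) return(as_community.abundances(x))
  if (ncol(x) < 2L) {
    stop_gsimpson("a community data frame needs a species column and a proportion column.",
                  class = "gsimpson_domain_error")
  }
  community(x[[2L]], labels = x[[1L]])
}

community_probs <- function(x) as_community(x)$prob

n_species <- function(x) nrow(as_community(x))

is_uniform <- function(p, tol = 1e-12) {
  max(abs(p - 1 / length(p))) <= tol
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("<community: %d species>\n", nrow(x)))
  NextMethod()
  invisible(x)
}
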