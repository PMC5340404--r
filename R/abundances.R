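#' Construct an observed abundance sample
#'
#' An `abundances` object holds the counts \eqn{n'_1, \dots, n'_K} of the
#' `K` species observed in a random sample of \eqn{n = \sum_s n'_s}
#' individuals. Only observed species are stored (all counts >= 1):
#' unobserved species carry \eqn{\hat p = 0} and contribute nothing to any
#' estimator, so they are never represented.
#'
#' @param counts Integer vector of per-species counts, all >= 1.
#' @param labels Optional unique species labels.
#' @param name Optional community name (carried as an attribute; used by
#'   printing and the command-line tool).
#' @return An `abundances` object: a tibble with columns `species` and
#'   `count`.
#' @examples
#' abundances(c(4, 2, 1))
#' @export
abundances <- function(counts, labels = NULL, name = NULL) {
  if (!is.numeric(counts) || length(counts) < 1L) {
    stop_gsimpson("`counts` must be a non-empty numeric vector.",
                  class = "gsimpson_domain_error")
  }
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != floor(counts))) {
    stop_gsimpson("all counts must be integers >= 1 (drop zero-count species before construction).",
                  class = "gsimpson_domain_error")
  }
  if (is.null(labels)) {
    labels <- names(counts) %||% paste0("sp", seq_along(counts))
  } else {
    labels <- as.character(labels)
  }
  if (length(labels) != length(counts) || anyDuplicated(labels)) {
    stop_gsimpson("species labels must be unique and match `counts` in length.",
                  class = "gsimpson_domain_error")
  }
  out <- tibble::tibble(species = labels, count = as.integer(counts))
  class(out) <- c("abundances", class(out))
  if (!is.null(name)) attr(out, "community_name") <- name
  out
}

#' Coerce to an abundance sample
#'
#' Accepts an `abundances` object (returned unchanged), a numeric count
#' vector, or a two-column data frame of (species, count). Zero-count rows
#' in a data frame are dropped with a message, matching the convention that
#' only observed species are represented.
#'
#' @param x Object to coerce.
#' @param ... Unused.
#' @return An `abundances` object.
#' @export
as_abundances <- function(x, ...) UseMethod("as_abundances")

#' @export
as_abundances.abundances <- function(x, ...) x

#' @export
as_abundances.numeric <- function(x, ...) abundances(x, labels = names(x))

#' @export
as_abundances.data.frame <- function(x, ...) {
  if (ncol(x) < 2L) {
    stop_gsimpson("an abundance data frame needs a species column and a count column.",
                  class = "gsimpson_domain_error")
  }
  species <- as.character(x[[1L]])
  counts <- x[[2L]]
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts != floor(counts)) ||
      any(counts < 0)) {
    bad <- which(!is.finite(counts) | counts != floor(counts) | counts < 0)[1L]
    stop_gsimpson(
      sprintf("counts must be non-negative integers; offending row %d (species '%s', count %s).",
              bad, species[bad], format(counts[bad])),
      class = "gsimpson_parse_error"
    )
  }
  drop <- counts == 0
  if (any(drop)) {
    message(sprintf("dropping %d zero-count species: %s", sum(drop),
                    paste(head(species[drop], 5L), collapse = ", ")))
    species <- species[!drop]
    counts <- counts[!drop]
  }
  if (length(counts) == 0L) {
    stop_gsimpson("no species with positive counts.", class = "gsimpson_domain_error")
  }
  abundances(counts, labels = species)
}

sample_size <- function(x) sum(as_abundances(x)$count)

observed_richness <- function(x) nrow(as_abundances(x))

#' @export
print.abundances <- function(x, ...) {
  nm <- attr(x, "community_name")
  cat(sprintf("<abundances%s: n = %d individuals, K = %d species>\n",
              if (is.null(nm)) "" else paste0(" '", nm, "'"),
              sum(x$count), nrow(x)))
  NextMethod()
  invisible(x)
}
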