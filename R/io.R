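#' Read an abundance table from a delimited file
#'
#' Expects a two-column table of (species label, count). The delimiter is
#' taken from `format` or guessed from the file extension; a header row is
#' auto-detected (present when the second field of the first row is not an
#' integer). Zero-count rows are dropped with a message; negative or
#' non-integer counts and duplicate labels are errors that name the
#' offending row.
#'
#' @param path Path to the file.
#' @param format `"tsv"`, `"csv"`, or `NULL` to infer from the extension
#'   (default tab).
#' @return An [abundances] sample, named after the file.
#' @export
read_abundances <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop_gsimpson(sprintf("file not found: %s", path), class = "gsimpson_io_error")
  }
  sep <- io_separator(path, format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_gsimpson(sprintf("empty abundance table: %s", path),
                  class = "gsimpson_parse_error")
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 2L)) {
    stop_gsimpson(
      sprintf("expected two columns (species, count); row %d of %s has %d.",
              which(ncols != 2L)[1L], path, ncols[which(ncols != 2L)[1L]]),
      class = "gsimpson_parse_error"
    )
  }
  m <- do.call(rbind, fields)
  # header row: second field not parseable as a number
  has_header <- is.na(suppressWarnings(as.numeric(trimws(m[1L, 2L]))))
  if (has_header) m <- m[-1L, , drop = FALSE]
  if (nrow(m) == 0L) {
    stop_gsimpson(sprintf("no data rows in %s", path), class = "gsimpson_parse_error")
  }
  species <- trimws(m[, 1L])
  raw <- trimws(m[, 2L])
  counts <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts))
  if (length(bad) > 0L) {
    stop_gsimpson(
      sprintf("row %d of %s: count '%s' for species '%s' is not a non-negative integer.",
              bad[1L] + has_header, path, raw[bad[1L]], species[bad[1L]]),
      class = "gsimpson_parse_error"
    )
  }
  if (anyDuplicated(species)) {
    dup <- species[duplicated(species)][1L]
    stop_gsimpson(sprintf("duplicate species label '%s' in %s.", dup, path),
                  class = "gsimpson_parse_error")
  }
  out <- as_abundances(data.frame(species = species, count = counts))
  attr(out, "community_name") <- tools::file_path_sans_ext(basename(path))
  out
}

#' Read a wide multi-community abundance table
#'
#' A species-by-community table: first column species labels, remaining
#' columns one count column per community (header row required, naming the
#' communities). Convenient for two-plot comparisons.
#'
#' @inheritParams read_abundances
#' @return Named list of [abundances] samples, one per community column.
#' @export
read_abundance_matrix <- function(path, format = NULL) {
  sep <- io_separator(path, format)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop_gsimpson("a wide table needs a species column plus at least one count column.",
                  class = "gsimpson_parse_error")
  }
  communities <- names(df)[-1L]
  out <- lapply(communities, function(nm) {
    smp <- as_abundances(df[, c(1L, match(nm, names(df)))])
    attr(smp, "community_name") <- nm
    smp
  })
  names(out) <- communities
  out
}

io_separator <- function(path, format) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  switch(match.arg(format, c("tsv", "csv")), tsv = "\t", csv = ",")
}

#' Write a profile to disk
#'
#' Serializes an entropy/diversity profile or a difference profile with the
#' fixed column schema `order`, `estimate`, `lower`, `upper`, `scale`,
#' `level` (a difference profile's `difference` column is written as
#' `estimate` with scale `"difference"`). TSV and JSON carry the same
#' schema and round-trip losslessly through [read_profile()].
#'
#' @param profile A [zeta_profile()] or [zeta_difference_profile()] result.
#' @param path Output path.
#' @param format `"tsv"` or `"json"` (default inferred from extension).
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  flat <- flatten_profile(profile)
  ok <- tryCatch({
    if (format == "json") {
      jsonlite::write_json(flat, path, digits = NA, auto_unbox = FALSE)
    } else {
      utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_gsimpson(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                  class = "gsimpson_io_error")
  }
  invisible(path)
}

flatten_profile <- function(profile) {
  if (inherits(profile, "zeta_difference_profile")) {
    data.frame(order = profile$order, estimate = profile$difference,
               lower = profile$lower, upper = profile$upper,
               scale = "difference", level = profile$level)
  } else if (inherits(profile, "zeta_profile")) {
    data.frame(order = profile$order, estimate = profile$estimate,
               lower = profile$lower, upper = profile$upper,
               scale = profile$scale, level = profile$level)
  } else {
    stop_gsimpson("`profile` must be a zeta_profile or zeta_difference_profile.",
                  class = "gsimpson_domain_error")
  }
}

#' Read a profile written by [write_profile()]
#'
#' @param path Path to a TSV or JSON profile file.
#' @param format `"tsv"` or `"json"` (default inferred from extension).
#' @return A tibble with columns `order`, `estimate`, `lower`, `upper`,
#'   `scale`, `level`.
#' @export
read_profile <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  df <- if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  }
  tibble::as_tibble(df)
}
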