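#' Attributed evidence
#'
#' A labelled entity (a pattern to match against, or a sample to classify)
#' described by one CBBA per attribute.
#'
#' @param id A single character label.
#' @param evidence Named list of `cbba` objects, one per attribute.
#' @return An object of class `attributed_evidence`.
#' @export
attributed_evidence <- function(id, evidence) {
  id <- as.character(id)
  stopifnot(length(id) == 1L, is.list(evidence))
  if (length(evidence) == 0L) {
    stop("attributed evidence needs at least one attribute", call. = FALSE)
  }
  if (is.null(names(evidence)) || any(!nzchar(names(evidence))) ||
      anyDuplicated(names(evidence))) {
    stop("evidence must be a list uniquely named by attribute", call. = FALSE)
  }
  ok <- vapply(evidence, inherits, logical(1), what = "cbba")
  if (!all(ok)) {
    stop("every attribute must carry a cbba object", call. = FALSE)
  }
  structure(list(id = id, evidence = evidence),
            class = "attributed_evidence")
}

#' @export
print.attributed_evidence <- function(x, ...) {
  cat(sprintf("Attributed evidence '%s' (%d attribute%s: %s)\n",
              x$id, length(x$evidence),
              if (length(x$evidence) == 1L) "" else "s",
              paste(names(x$evidence), collapse = ", ")))
  invisible(x)
}

#' Minimum-distance multi-attribute classification
#'
#' Assigns a sample to the pattern at minimal (weighted) multi-attribute
#' betting-commitment distance: the per-attribute [bcd()] values are
#' averaged (or weighted by `weights`) via [attribute_distance()], and the
#' pattern attaining the minimum is chosen. Ties at the minimal distance
#' are broken in favour of the earliest pattern in `patterns` and flagged
#' in the result.
#'
#' @param sample An [attributed_evidence()] object.
#' @param patterns A (non-empty) list of [attributed_evidence()] objects
#'   with the same attribute set as `sample`.
#' @param weights Named attribute weights summing to 1, or `NULL` for the
#'   uniform scheme.
#' @return An object of class `classification_result` with fields
#'   `sample_id`, `distances` (named by pattern), `chosen`, `ranking`
#'   (pattern ids sorted by ascending distance), and `tie` (logical).
#' @examples
#' f <- fod(c("y", "n"))
#' pat <- function(id, m) attributed_evidence(id, list(
#'   a1 = cbba(f, list("y", "n"), c(m, 1 - m))))
#' res <- classify_sample(pat("s", 0.7), list(pat("p1", 0.9), pat("p2", 0.6)))
#' res$chosen
#' @export
classify_sample <- function(sample, patterns, weights = NULL) {
  stopifnot(inherits(sample, "attributed_evidence"))
  if (inherits(patterns, "attributed_evidence")) patterns <- list(patterns)
  if (length(patterns) == 0L) {
    stop("at least one pattern is required", call. = FALSE)
  }
  ids <- unname(vapply(patterns, function(p) p$id, character(1)))
  if (anyDuplicated(ids)) {
    stop("pattern ids must be unique", call. = FALSE)
  }
  d <- vapply(patterns, function(p) attribute_distance(sample, p, weights),
              numeric(1))
  names(d) <- ids
  best <- unname(which.min(d))      # earliest index at the minimum
  tie <- sum(d == d[[best]]) > 1L
  structure(list(
    sample_id = sample$id,
    distances = d,
    chosen = ids[best],
    ranking = ids[order(d)],
    tie = tie
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, digits = 4, ...) {
  cat(sprintf("Classification of sample '%s'\n", x$sample_id))
  df <- data.frame(pattern = names(x$distances),
                   distance = round(unname(x$distances), digits),
                   rank = match(names(x$distances), x$ranking),
                   chosen = names(x$distances) == x$chosen)
  print(df[order(df$rank), ], row.names = FALSE)
  if (x$tie) cat("note: minimal distance tied; earliest pattern chosen\n")
  invisible(x)
}
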