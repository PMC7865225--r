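#' Frame of discernment
#'
#' Construct the frame of discernment: the ordered, finite set of mutually
#' exclusive and exhaustive hypotheses over which evidence is expressed.
#' Every subset of the frame is addressed internally by a bitmask over this
#' element order, so the order given here is the canonical one.
#'
#' @param elements Character vector of distinct, non-empty element labels.
#' @param cap Maximum number of elements permitted (default 20). Downstream
#'   operations enumerate all \eqn{2^n - 1} non-empty subsets, so the frame
#'   size is capped to keep those enumerations tractable.
#' @return An object of class `fod` with fields `elements` and `n`.
#' @examples
#' fod(c("a", "b", "c"))
#' @export
fod <- function(elements, cap = 20L) {
  elements <- as.character(elements)
  if (length(elements) == 0L) {
    stop("frame of discernment must contain at least one element", call. = FALSE)
  }
  if (anyNA(elements) || any(!nzchar(elements))) {
    stop("frame elements must be non-missing, non-empty labels", call. = FALSE)
  }
  if (anyDuplicated(elements)) {
    stop("frame elements must be unique; duplicated: ",
         paste(unique(elements[duplicated(elements)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(elements) > cap) {
    stop(sprintf("frame has %d elements, exceeding the cap of %d",
                 length(elements), cap), call. = FALSE)
  }
  structure(list(elements = elements, n = length(elements)),
            class = "fod")
}

#' @export
print.fod <- function(x, ...) {
  cat(sprintf("Frame of discernment with %d element%s: {%s}\n",
              x$n, if (x$n == 1L) "" else "s",
              paste(x$elements, collapse = ", ")))
  invisible(x)
}

#' @export
format.fod <- function(x, ...) {
  paste0("{", paste(x$elements, collapse = ","), "}")
}

same_frame <- function(a, b) {
  identical(a$elements, b$elements)
}

stop_frame_mismatch <- function() {
  stop("CBBAs are defined over different frames of discernment", call. = FALSE)
}

# ---- subset (hypothesis) keys -----------------------------------------------
# A hypothesis is a non-empty subset of the frame, keyed canonically by the
# bitmask over frame order: bit j-1 set <=> element j is a member. Keys are
# stored as doubles so frames up to the cap of 20 stay exact (2^20 < 2^53).

subset_key <- function(frame, members) {
  members <- as.character(members)
  idx <- match(members, frame$elements)
  if (anyNA(idx)) {
    stop("unknown frame element(s): ",
         paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("subset contains duplicated element(s): ",
         paste(unique(members[duplicated(idx)]), collapse = ", "),
         call. = FALSE)
  }
  sum(2^(idx - 1))
}

key_members <- function(frame, key) {
  frame$elements[bitwAnd(as.integer(key) %/% 2^(seq_len(frame$n) - 1L), 1L) == 1L]
}

key_cardinality <- function(key) {
  n <- 0L
  key <- as.integer(key)
  while (key > 0L) {
    n <- n + bitwAnd(key, 1L)
    key <- bitwShiftR(key, 1L)
  }
  n
}

# vectorised popcount for key vectors
key_cardinalities <- function(keys) {
  vapply(keys, key_cardinality, integer(1))
}

format_subset <- function(frame, key) {
  paste0("{", paste(key_members(frame, key), collapse = ","), "}")
}

#' Enumerate all non-empty subsets of a frame
#'
#' Lists every non-empty subset of the frame in a deterministic order:
#' ascending cardinality, then ascending canonical bitmask key. This is the
#' order used by [betting_commitment_table()] and all reports.
#'
#' @param frame A [fod()] object.
#' @return A list of character vectors, one per subset, of length
#'   \eqn{2^n - 1}. The canonical bitmask keys are attached as attribute
#'   `keys`.
#' @examples
#' enumerate_subsets(fod(c("a", "b")))
#' @export
enumerate_subsets <- function(frame) {
  stopifnot(inherits(frame, "fod"))
  keys <- seq_len(2^frame$n - 1)
  card <- key_cardinalities(keys)
  keys <- keys[order(card, keys)]
  out <- lapply(keys, function(k) key_members(frame, k))
  attr(out, "keys") <- keys
  out
}
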