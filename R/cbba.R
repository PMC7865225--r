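#' Complex mass value from polar form
#'
#' Converts a polar mass specification, magnitude and phase, into the
#' Cartesian complex number used internally. A complex mass
#' \eqn{M(A) = m(A) e^{i\theta(A)}} has magnitude \eqn{m(A) \in [0, 1]} and
#' phase \eqn{\theta(A) \in [-\pi, \pi]}.
#'
#' @param magnitude Numeric vector of magnitudes in `[0, 1]`.
#' @param phase Numeric vector of phases in radians, in `[-pi, pi]`.
#' @return A complex vector `magnitude * exp(1i * phase)`.
#' @seealso [from_polar_tan()] for the `e^{i arctan(r)}` notation common in
#'   tabulated CBBAs.
#' @examples
#' from_polar(0.9055, atan(0.1111)) # ~ 0.9 + 0.1i
#' @export
from_polar <- function(magnitude, phase) {
  magnitude <- as.numeric(magnitude)
  phase <- as.numeric(phase)
  tol <- 1e-9
  if (anyNA(magnitude) || any(magnitude < -tol) || any(magnitude > 1 + tol)) {
    stop("magnitude must lie in [0, 1]", call. = FALSE)
  }
  if (anyNA(phase) || any(abs(phase) > pi + tol)) {
    stop("phase must lie in [-pi, pi] radians", call. = FALSE)
  }
  complex(real = magnitude * cos(phase), imaginary = magnitude * sin(phase))
}

#' Complex mass value from magnitude and phase tangent
#'
#' Convenience constructor for mass values written as
#' \eqn{m \, e^{i \arctan(r)}}: the phase is `atan(tangent)`, so it always
#' falls in `(-pi/2, pi/2)` (non-negative real part).
#'
#' @param magnitude Numeric vector of magnitudes in `[0, 1]`.
#' @param tangent Numeric vector: the tangent of the phase.
#' @return A complex vector.
#' @examples
#' from_polar_tan(0.8062, 0.1250) # ~ 0.8 + 0.1i
#' @export
from_polar_tan <- function(magnitude, tangent) {
  from_polar(magnitude, atan(as.numeric(tangent)))
}

#' Complex basic belief assignment (CBBA)
#'
#' Builds and validates a complex basic belief assignment: a map from
#' non-empty subsets of the frame to complex masses whose magnitudes lie in
#' `[0, 1]` and whose complex sum is exactly \eqn{1 + 0i}. The empty set
#' always carries mass zero. Entries with zero magnitude may be supplied
#' (they are retained for display) but are not focal elements.
#'
#' @param frame A [fod()] object.
#' @param subsets List of character vectors, each a non-empty subset of the
#'   frame. A single character vector is treated as one subset.
#' @param mass Complex (or numeric) vector of masses, one per subset.
#' @param tol_norm Absolute tolerance on the complex-sum residual
#'   `|sum(mass) - 1|`. Defaults to `1e-9`; use [cbba_tol()] with
#'   `paper_rounded = TRUE` (i.e. `1e-3`) for inputs transcribed from
#'   4-decimal rounded tables.
#' @return An object of class `cbba` with fields `frame`, `keys` (canonical
#'   bitmask subset keys), and `mass` (complex vector).
#' @examples
#' f <- fod(c("a", "b", "c"))
#' m <- cbba(f, list("a", c("a", "b"), c("a", "b", "c")),
#'           c(0.4 + 0.1i, 0.4 - 0.1i, 0.2))
#' @export
cbba <- function(frame, subsets, mass, tol_norm = 1e-9) {
  stopifnot(inherits(frame, "fod"))
  if (is.character(subsets)) subsets <- list(subsets)
  mass <- as.complex(mass)
  if (length(subsets) != length(mass)) {
    stop("subsets and mass must have the same length", call. = FALSE)
  }
  keys <- vapply(subsets, function(s) subset_key(frame, s), numeric(1))
  if (any(keys == 0)) {
    stop("the empty set cannot carry mass in a CBBA", call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    stop("duplicated subset(s): ",
         paste(vapply(dup, function(k) format_subset(frame, k), character(1)),
               collapse = ", "), call. = FALSE)
  }
  ord <- order(key_cardinalities(keys), keys)
  M <- structure(list(frame = frame, keys = keys[ord], mass = mass[ord]),
                 class = "cbba")
  rep <- validate_cbba(M, tol_norm = tol_norm)
  if (!rep$valid) {
    stop("invalid CBBA: ", paste(rep$issues, collapse = "; "), call. = FALSE)
  }
  M
}

#' Default normalization tolerance
#'
#' Exact Cartesian input is checked at `1e-9`; input transcribed from
#' 4-decimal rounded magnitude/phase tables accumulates rounding in the
#' complex sum, so it is checked at `1e-3`.
#'
#' @param paper_rounded Logical; is the input transcribed from rounded
#'   printed values?
#' @return A numeric tolerance.
#' @export
cbba_tol <- function(paper_rounded = FALSE) {
  if (isTRUE(paper_rounded)) 1e-3 else 1e-9
}

#' Validate a CBBA
#'
#' Checks the defining invariants of a complex basic belief assignment and
#' reports every violation rather than stopping at the first: the empty set
#' carries no mass, every magnitude lies in `[0, 1]`, and the complex masses
#' sum to \eqn{1 + 0i} within `tol_norm`.
#'
#' @param M A `cbba` object (or a bare list with `frame`, `keys`, `mass`).
#' @param tol_norm Absolute tolerance on `|sum(mass) - 1|`.
#' @param tol_mag Absolute tolerance on the magnitude range check.
#' @return A list with `valid` (logical), `issues` (character vector),
#'   and `residual` (the complex value `sum(mass) - 1`).
#' @export
validate_cbba <- function(M, tol_norm = 1e-9, tol_mag = 1e-9) {
  issues <- character(0)
  if (any(M$keys == 0)) {
    issues <- c(issues, "the empty set carries non-zero mass")
  }
  mag <- Mod(M$mass)
  if (any(mag > 1 + tol_mag)) {
    bad <- which(mag > 1 + tol_mag)
    issues <- c(issues, sprintf(
      "magnitude out of [0, 1] for %s (|mass| = %.4f)",
      paste(vapply(M$keys[bad], function(k) format_subset(M$frame, k),
                   character(1)), collapse = ", "),
      max(mag[bad])))
  }
  residual <- sum(M$mass) - (1 + 0i)
  if (Mod(residual) > tol_norm) {
    issues <- c(issues, sprintf(
      "complex masses sum to %s, residual %s exceeds tol %g",
      format(sum(M$mass), digits = 6), format(residual, digits = 6), tol_norm))
  }
  list(valid = length(issues) == 0L, issues = issues, residual = residual)
}

#' Focal elements of a CBBA
#'
#' The focal elements are the subsets carrying strictly positive mass
#' magnitude. Zero-magnitude entries supplied at construction are excluded.
#'
#' @param M A `cbba` object.
#' @return A list of character vectors (one per focal subset), with the
#'   canonical keys attached as attribute `keys`.
#' @export
focal_elements <- function(M) {
  keep <- Mod(M$mass) > 0
  out <- lapply(M$keys[keep], function(k) key_members(M$frame, k))
  attr(out, "keys") <- M$keys[keep]
  out
}

#' Is a CBBA classical?
#'
#' A CBBA reduces to a classical (real, non-negative) basic belief
#' assignment when every mass has negligible imaginary part and
#' non-negative real part. Classical CBBAs are exactly the domain on which
#' the complex machinery reduces to ordinary Dempster-Shafer theory.
#'
#' @param M A `cbba` object.
#' @param tol Tolerance on `|Im|` and on negativity of `Re`.
#' @return Logical.
#' @export
is_classical <- function(M, tol = 1e-9) {
  all(abs(Im(M$mass)) <= tol) && all(Re(M$mass) >= -tol)
}

#' Mass carried by a subset
#'
#' @param M A `cbba` object.
#' @param subset Character vector of member labels.
#' @return The complex mass of `subset` (0 if the subset is not stored).
#' @export
cbba_mass <- function(M, subset) {
  key <- subset_key(M$frame, subset)
  hit <- which(M$keys == key)
  if (length(hit) == 0L) 0 + 0i else M$mass[hit]
}

#' The vacuous CBBA
#'
#' Total ignorance: all mass on the full frame. The neutral element of
#' [combine_cbba()].
#'
#' @param frame A [fod()] object.
#' @return A `cbba` object with `M(frame) = 1`.
#' @export
vacuous_cbba <- function(frame) {
  cbba(frame, list(frame$elements), 1 + 0i)
}

#' @export
print.cbba <- function(x, digits = 4, ...) {
  cat(sprintf("CBBA over %s\n", format(x$frame)))
  lab <- vapply(x$keys, function(k) format_subset(x$frame, k), character(1))
  df <- data.frame(
    subset = lab,
    mass = format(x$mass, digits = digits),
    magnitude = round(Mod(x$mass), digits),
    phase = round(Arg(x$mass), digits)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
format.cbba <- function(x, ...) {
  lab <- vapply(x$keys, function(k) format_subset(x$frame, k), character(1))
  paste(sprintf("%s=%s", lab, format(x$mass, digits = 4)), collapse = ", ")
}

#' @exportS3Method base::all.equal
all.equal.cbba <- function(target, current, tolerance = 1e-12, ...) {
  if (!same_frame(target$frame, current$frame)) return("frame mismatch")
  n_keys <- 2^target$frame$n - 1
  mt <- mv <- complex(n_keys)
  mt[target$keys] <- target$mass
  mv[current$keys] <- current$mass
  d <- max(Mod(mt - mv))
  if (d <= tolerance) TRUE else sprintf("max mass difference %g", d)
}
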