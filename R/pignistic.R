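# Complex pignistic transformation: each focal mass is split equally over
# its member singletons (division by the cardinality of the *focal* set),
# and subset values are additive accumulations of singleton values. An
# alternative normalization dividing by the cardinality of the *target*
# subset is kept behind `method = "target"` for auditing; it is not
# additive and is not the default.

# complex pignistic value of every singleton, in frame order
cpt_singletons <- function(M) {
  out <- complex(M$frame$n)
  keys <- as.integer(M$keys)
  card <- key_cardinalities(keys)
  for (i in seq_along(keys)) {
    members <- bitwAnd(keys[i] %/% 2^(seq_len(M$frame$n) - 1L), 1L) == 1L
    out[members] <- out[members] + M$mass[i] / card[i]
  }
  out
}

#' Complex pignistic value of a single element
#'
#' The complex pignistic transformation of element \eqn{\phi_j}: every focal
#' mass containing \eqn{\phi_j} contributes its mass divided by the focal
#' set's cardinality,
#' \deqn{CPT(\phi_j) = \sum_{A_i \ni \phi_j} M(A_i) / |A_i|.}
#' For a CBBA whose focal elements are all singletons (a probability
#' distribution), this returns the element's own mass.
#'
#' @param M A `cbba` object.
#' @param element A single frame element label.
#' @return A complex scalar.
#' @export
cpt_singleton <- function(M, element) {
  stopifnot(inherits(M, "cbba"))
  idx <- match(as.character(element), M$frame$elements)
  if (length(idx) != 1L || is.na(idx)) {
    stop("unknown frame element: ", element, call. = FALSE)
  }
  cpt_singletons(M)[idx]
}

#' Complex pignistic value of a subset
#'
#' Additive extension of [cpt_singleton()] to arbitrary non-empty subsets:
#' \deqn{CPT(A) = \sum_{\phi_j \in A} CPT(\phi_j)
#'             = \sum_{A_i} M(A_i) |A_i \cap A| / |A_i|.}
#' `cpt(M, frame$elements)` is always \eqn{1 + 0i} for a valid CBBA.
#'
#' @param M A `cbba` object.
#' @param subset Character vector of member labels (non-empty).
#' @param method `"focal"` (default) divides each mass by the cardinality of
#'   its focal set; `"target"` divides by the cardinality of `subset`
#'   instead. Only the default is additive and reproduces the reference
#'   betting commitments; the alternative is provided for auditing.
#' @return A complex scalar.
#' @export
cpt <- function(M, subset, method = c("focal", "target")) {
  stopifnot(inherits(M, "cbba"))
  method <- match.arg(method)
  key <- subset_key(M$frame, subset)
  if (key == 0) stop("subset must be non-empty", call. = FALSE)
  card_A <- key_cardinality(key)
  keys <- as.integer(M$keys)
  inter <- key_cardinalities(bitwAnd(keys, as.integer(key)))
  if (method == "focal") {
    sum(M$mass * inter / key_cardinalities(keys))
  } else {
    sum(M$mass * inter / card_A)
  }
}

#' Betting commitment of a subset
#'
#' The betting commitment is the modulus of the complex pignistic value:
#' \eqn{BetC(A) = |CPT(A)|}. It is the real-valued quantity compared across
#' CBBAs by the betting-commitment distance [bcd()].
#'
#' @inheritParams cpt
#' @return A non-negative real scalar.
#' @examples
#' f <- fod(c("a", "b", "c", "d"))
#' m1 <- cbba(f, list(c("a", "b"), "c"), c(0.9 + 0.1i, 0.1 - 0.1i))
#' betting_commitment(m1, c("a", "b")) # 0.9055
#' @export
betting_commitment <- function(M, subset, method = c("focal", "target")) {
  Mod(cpt(M, subset, method = match.arg(method)))
}

#' Betting commitments over all subsets
#'
#' Evaluates the complex pignistic transformation and the betting
#' commitment for every non-empty subset of the frame. Singleton values are
#' computed once and subset values are formed by additive accumulation, so
#' the table costs \eqn{O(n 2^n)} complex additions.
#'
#' @param M A `cbba` object.
#' @return An object of class `betc_table`: a data frame with columns
#'   `subset` (label), `cardinality`, `cpt` (complex), and `betc` (real),
#'   ordered as [enumerate_subsets()], with the canonical keys as attribute
#'   `keys`.
#' @export
betting_commitment_table <- function(M) {
  stopifnot(inherits(M, "cbba"))
  z <- cpt_all_subsets(M)          # indexed by bitmask
  subs <- enumerate_subsets(M$frame)
  keys <- attr(subs, "keys")
  lab <- vapply(keys, function(k) format_subset(M$frame, k), character(1))
  out <- data.frame(subset = lab,
                    cardinality = key_cardinalities(keys),
                    stringsAsFactors = FALSE)
  out$cpt <- z[keys]
  out$betc <- Mod(out$cpt)
  attr(out, "keys") <- keys
  class(out) <- c("betc_table", "data.frame")
  out
}

# Complex pignistic value of every non-empty subset, returned as a vector
# indexed by bitmask (position k = subset with key k). Built by the doubling
# construction: appending element j maps mask -> mask + 2^(j-1), so one
# concatenation per element yields all 2^n subset sums in O(2^n) additions.
cpt_all_subsets <- function(M) {
  s <- cpt_singletons(M)
  z <- 0 + 0i
  for (j in seq_along(s)) z <- c(z, z + s[j])
  z[-1]
}
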