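#' Betting-commitment-based distance between CBBAs
#'
#' The BCD between two CBBAs is the largest absolute difference between
#' their betting commitments over all non-empty subsets of the frame:
#' \deqn{d_{BCD}(M_u, M_v) = \max_{A \subseteq \Phi, A \neq \emptyset}
#'       \left| BetC_{M_u}(A) - BetC_{M_v}(A) \right|.}
#' The max aggregator (rather than min or mean) is what lets the distance
#' separate strongly conflicting pairs. BCD is non-negative, symmetric, and
#' satisfies the triangle inequality; it is a pseudo-metric: distinct CBBAs
#' with identical pignistic transforms (e.g. a uniform split of a focal set
#' versus the focal set itself) are at distance 0.
#'
#' On classical inputs BCD coincides with Liu's distance between betting
#' commitments, [difbetp()].
#'
#' @param Mu,Mv `cbba` objects over the same frame.
#' @return A non-negative real scalar.
#' @examples
#' f <- fod(c("a", "b", "c", "d"))
#' m1 <- cbba(f, list(c("a", "b"), "c"), c(0.9 + 0.1i, 0.1 - 0.1i))
#' m2 <- cbba(f, list("c", "d"), c(0.1 - 0.1i, 0.9 + 0.1i))
#' bcd(m1, m2)
#' @export
bcd <- function(Mu, Mv) {
  stopifnot(inherits(Mu, "cbba"), inherits(Mv, "cbba"))
  if (!same_frame(Mu$frame, Mv$frame)) stop_frame_mismatch()
  zu <- cpt_all_subsets(Mu)
  zv <- cpt_all_subsets(Mv)
  max(abs(Mod(zu) - Mod(zv)))
}

#' Liu's distance between betting commitments of classical BBAs
#'
#' The classical distance between betting commitments (difBetP): the
#' largest absolute difference of the real pignistic probabilities over all
#' non-empty subsets, computed entirely in real arithmetic. Defined only
#' for classical inputs ([is_classical()]); on that domain it equals
#' [bcd()] exactly.
#'
#' @param mu,mv Classical `cbba` objects over the same frame.
#' @param tol Tolerance used by the classicality check.
#' @return A non-negative real scalar.
#' @export
difbetp <- function(mu, mv, tol = 1e-9) {
  stopifnot(inherits(mu, "cbba"), inherits(mv, "cbba"))
  if (!same_frame(mu$frame, mv$frame)) stop_frame_mismatch()
  if (!is_classical(mu, tol) || !is_classical(mv, tol)) {
    stop("difbetp is defined for classical BBAs only; use bcd() for CBBAs",
         call. = FALSE)
  }
  pu <- Re(cpt_singletons(mu))
  pv <- Re(cpt_singletons(mv))
  # BetP is additive over disjoint singletons, so the maximizing subset
  # collects all positive (or all negative) singleton differences.
  d <- pu - pv
  max(sum(d[d > 0]), -sum(d[d < 0]), 0)
}

#' Multi-attribute distance between evidence sets
#'
#' Aggregates the per-attribute [bcd()] between a sample and a pattern that
#' carry one CBBA per attribute. With `weights = NULL` every attribute gets
#' weight \eqn{1/\eta} (the plain average); otherwise the given weights,
#' which must be non-negative and sum to 1, are used:
#' \deqn{d(s, p) = \sum_\kappa w_\kappa \,
#'       d_{BCD}(M_s^{a_\kappa}, M_p^{a_\kappa}).}
#'
#' @param sample,pattern [attributed_evidence()] objects over identical
#'   attribute sets (per-attribute frames must match).
#' @param weights Named numeric vector of attribute weights summing to 1,
#'   or `NULL` for uniform weighting.
#' @return A non-negative real scalar.
#' @export
attribute_distance <- function(sample, pattern, weights = NULL) {
  stopifnot(inherits(sample, "attributed_evidence"),
            inherits(pattern, "attributed_evidence"))
  attrs <- names(sample$evidence)
  if (!setequal(attrs, names(pattern$evidence))) {
    stop(sprintf("attribute sets differ between '%s' and '%s'",
                 sample$id, pattern$id), call. = FALSE)
  }
  w <- resolve_weights(weights, attrs)
  d <- vapply(attrs, function(a) bcd(sample$evidence[[a]],
                                     pattern$evidence[[a]]), numeric(1))
  sum(w[attrs] * d)
}

# uniform weights when NULL; otherwise validate coverage and normalization
resolve_weights <- function(weights, attrs) {
  if (is.null(weights)) {
    w <- rep(1 / length(attrs), length(attrs))
    names(w) <- attrs
    return(w)
  }
  if (is.null(names(weights)) || !setequal(names(weights), attrs)) {
    stop("weights must be named by the attribute labels: ",
         paste(attrs, collapse = ", "), call. = FALSE)
  }
  if (any(weights < 0)) {
    stop("attribute weights must be non-negative", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-6) {
    stop(sprintf("attribute weights must sum to 1 (got %.6f)", sum(weights)),
         call. = FALSE)
  }
  weights
}
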