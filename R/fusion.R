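#' Conflict coefficient between two CBBAs
#'
#' The conflict coefficient K is the complex sum of the pairwise mass
#' products over all pairs of focal elements with empty intersection:
#' \deqn{K = \sum_{A_i \cap A_h = \emptyset} M_u(A_i) M_v(A_h).}
#' Its modulus |K| is the classical conflict measure. For complex masses
#' |K| can exceed 1.
#'
#' @param Mu,Mv `cbba` objects over the same frame.
#' @return An object of class `conflict_coefficient` with fields `value`
#'   (complex K) and `modulus` (|K|).
#' @examples
#' f <- fod(c("a", "b"))
#' m1 <- cbba(f, list("a"), 1)
#' m2 <- cbba(f, list("b"), 1)
#' conflict_coefficient(m1, m2) # total conflict, K = 1
#' @export
conflict_coefficient <- function(Mu, Mv) {
  stopifnot(inherits(Mu, "cbba"), inherits(Mv, "cbba"))
  if (!same_frame(Mu$frame, Mv$frame)) stop_frame_mismatch()
  K <- 0 + 0i
  for (i in seq_along(Mu$keys)) {
    disjoint <- bitwAnd(as.integer(Mu$keys[i]), as.integer(Mv$keys)) == 0L
    if (any(disjoint)) {
      K <- K + Mu$mass[i] * sum(Mv$mass[disjoint])
    }
  }
  structure(list(value = K, modulus = Mod(K)),
            class = "conflict_coefficient")
}

#' @export
print.conflict_coefficient <- function(x, digits = 4, ...) {
  cat(sprintf("K  = %s  (magnitude %.*f, phase %.*f rad)\n|K| = %.*f\n",
              format(x$value, digits = digits),
              digits, Mod(x$value), digits, Arg(x$value),
              digits, x$modulus))
  invisible(x)
}

#' Complex Dempster rule of combination
#'
#' Fuses two independent CBBAs by the complex generalization of Dempster's
#' rule: products of masses over pairs of focal elements are accumulated on
#' the pairwise intersections and renormalized by complex division by
#' \eqn{1 - K}, where K is the [conflict_coefficient()]. The empty set
#' receives mass zero. The rule is commutative and associative, and the
#' vacuous CBBA is its neutral element.
#'
#' @param Mu,Mv `cbba` objects over the same frame.
#' @param tol_k Guard against (near-)total conflict: if `|1 - K| < tol_k`
#'   the combination is undefined and an error is raised.
#' @return The fused `cbba`.
#' @examples
#' f <- fod(c("a", "b", "c"))
#' m1 <- cbba(f, list("a", c("a", "b")), c(0.6, 0.4))
#' m2 <- cbba(f, list("a", c("a", "b", "c")), c(0.5, 0.5))
#' combine_cbba(m1, m2)
#' @export
combine_cbba <- function(Mu, Mv, tol_k = 1e-9) {
  stopifnot(inherits(Mu, "cbba"), inherits(Mv, "cbba"))
  if (!same_frame(Mu$frame, Mv$frame)) stop_frame_mismatch()
  K <- conflict_coefficient(Mu, Mv)$value
  denom <- (1 + 0i) - K
  if (Mod(denom) < tol_k) {
    stop(sprintf(
      "total conflict: |1 - K| = %g < %g (K = %s); combination undefined",
      Mod(denom), tol_k, format(K, digits = 6)), call. = FALSE)
  }
  # accumulate products on intersection keys, focal elements only
  fu <- Mod(Mu$mass) > 0
  fv <- Mod(Mv$mass) > 0
  ku <- as.integer(Mu$keys[fu]); mu <- Mu$mass[fu]
  kv <- as.integer(Mv$keys[fv]); mv <- Mv$mass[fv]
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(ku)) {
    inter <- bitwAnd(ku[i], kv)
    prods <- mu[i] * mv
    for (j in which(inter != 0L)) {
      key <- as.character(inter[j])
      prev <- if (is.null(acc[[key]])) 0 + 0i else acc[[key]]
      acc[[key]] <- prev + prods[j]
    }
  }
  keys <- as.numeric(ls(acc))
  if (length(keys) == 0L) {
    stop("combination produced no non-empty intersection", call. = FALSE)
  }
  mass <- vapply(as.character(keys), function(k) acc[[k]], complex(1)) / denom
  subsets <- lapply(keys, function(k) key_members(Mu$frame, k))
  cbba(Mu$frame, subsets, mass, tol_norm = 1e-6)
}
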