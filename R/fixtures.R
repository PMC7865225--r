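# Reference examples for complex evidence theory, stored in exact Cartesian
# form. Published tabulations of CBBAs usually print the polar form
# m e^{i arctan(r)} rounded to 4 decimals; the underlying masses here are
# round one/two-decimal complex numbers. Each entry therefore stores the
# exact Cartesian value together with the rounded printed magnitude, and
# the loader cross-checks |z| against the printed magnitude within 5e-5 to
# guard against transcription drift.

# entry helper: exact re/im plus the printed (possibly rounded) magnitude
fx_entry <- function(subset, re, im, printed) {
  list(subset = subset, z = complex(real = re, imaginary = im),
       printed = printed)
}

fx_cbba <- function(frame, entries) {
  for (e in entries) {
    drift <- abs(Mod(e$z) - e$printed)
    if (drift > 5e-5) {
      stop(sprintf(
        "fixture drift: |%s| = %.6f differs from printed magnitude %.4f",
        format(e$z), Mod(e$z), e$printed), call. = FALSE)
    }
  }
  cbba(frame,
       lapply(entries, `[[`, "subset"),
       vapply(entries, `[[`, complex(1), "z"))
}

phi <- function(i) paste0("phi", i)

#' Reference examples
#'
#' Returns one of the package's built-in worked examples: small CBBA pairs
#' used throughout the documentation and tests, stored in exact Cartesian
#' form together with the rounded reference values they reproduce
#' (conflict modulus `|K|`, betting commitments, distances). Available
#' names:
#' \describe{
#'   \item{`ex1`}{Two highly conflicting CBBAs on a 4-element frame;
#'     `|K| = 1.0002`.}
#'   \item{`ex2`}{Two identical CBBAs on a 3-element frame; `|K| = 0`.}
#'   \item{`ex3`}{Two identical uniform singleton BBAs on a 4-element
#'     frame, where `|K| = 0.75` despite the sources agreeing — the case
#'     motivating a betting-commitment distance.}
#'   \item{`ex8_case1`, `ex8_case2`, `ex8_case3`}{Three CBBA pairs on a
#'     5-element frame with reference `|K|` and BCD values.}
#'   \item{`application`}{A three-pattern, three-attribute medical
#'     diagnosis task on the frame `{y, n}`: patterns `p1`-`p3`, sample
#'     `s1`, with reference uniform and weighted multi-attribute
#'     distances.}
#' }
#'
#' @param name One of the fixture names above.
#' @return A list with fields `name`, `frame`, `cbbas` (named list of
#'   `cbba` objects; for `application`, named lists of
#'   [attributed_evidence()] under `patterns` and `sample` plus `weights`),
#'   and `expected` (named list of reference values, each with `value` and
#'   `tol`).
#' @examples
#' fx <- cet_example("ex1")
#' conflict_coefficient(fx$cbbas$M1, fx$cbbas$M2)$modulus
#' @export
cet_example <- function(name = c("ex1", "ex2", "ex3", "ex8_case1",
                                 "ex8_case2", "ex8_case3", "application")) {
  name <- match.arg(name)
  switch(name,
    ex1 = {
      f <- fod(phi(1:4))
      M1 <- fx_cbba(f, list(
        fx_entry(phi(1:2), 0.9, 0.1, 0.9055),
        fx_entry(phi(3), 0.1, -0.1, 0.1414),
        fx_entry(phi(4), 0, 0, 0)))
      M2 <- fx_cbba(f, list(
        fx_entry(phi(1:2), 0, 0, 0),
        fx_entry(phi(3), 0.1, -0.1, 0.1414),
        fx_entry(phi(4), 0.9, 0.1, 0.9055)))
      list(name = name, frame = f, cbbas = list(M1 = M1, M2 = M2),
           expected = list(
             K_mod = list(value = 1.0002, tol = 5e-4),
             betc_M1 = list(value = c("phi1,phi2" = 0.9055,
                                      "phi3" = 0.1414, "phi4" = 0),
                            tol = 5e-4),
             betc_M2 = list(value = c("phi1,phi2" = 0,
                                      "phi3" = 0.1414, "phi4" = 0.9055),
                            tol = 5e-4)))
    },
    ex2 = {
      f <- fod(phi(1:3))
      entries <- list(
        fx_entry(phi(1), 0.4, 0.1, 0.4123),
        fx_entry(phi(1:2), 0.4, -0.1, 0.4123),
        fx_entry(phi(1:3), 0.2, 0, 0.2))
      M1 <- fx_cbba(f, entries)
      M2 <- fx_cbba(f, entries)
      list(name = name, frame = f, cbbas = list(M1 = M1, M2 = M2),
           expected = list(
             K_mod = list(value = 0, tol = 5e-4),
             # betting commitments of M1 for {phi1}, {phi1,phi2}, frame
             betc_M1 = list(value = c("phi1" = 0.6685,
                                      "phi1,phi2" = 0.9333,
                                      "phi1,phi2,phi3" = 1.0000),
                            tol = 5e-4)))
    },
    ex3 = {
      f <- fod(phi(1:4))
      entries <- lapply(1:4, function(i) fx_entry(phi(i), 0.25, 0, 0.25))
      M1 <- fx_cbba(f, entries)
      M2 <- fx_cbba(f, entries)
      list(name = name, frame = f, cbbas = list(M1 = M1, M2 = M2),
           expected = list(
             K_mod = list(value = 0.75, tol = 5e-4),
             betc_singletons = list(value = rep(0.25, 4), tol = 5e-4)))
    },
    ex8_case1 = {
      f <- fod(phi(1:5))
      M1 <- fx_cbba(f, list(
        fx_entry(phi(1:2), 0.8, 0.1, 0.8062),
        fx_entry(phi(3), 0.1, -0.1, 0.1414),
        fx_entry(phi(4), 0.1, 0, 0.1)))
      M2 <- fx_cbba(f, list(
        fx_entry(phi(1:2), 0.1, 0, 0.1),
        fx_entry(phi(3), 0.1, -0.1, 0.1414),
        fx_entry(phi(4), 0.8, 0.1, 0.8062)))
      list(name = name, frame = f, cbbas = list(M1 = M1, M2 = M2),
           expected = list(
             K_mod = list(value = 0.8400, tol = 5e-4),
             bcd = list(value = 0.7062, tol = 5e-4)))
    },
    ex8_case2 = {
      f <- fod(phi(1:5))
      M1 <- fx_cbba(f, list(
        fx_entry(phi(c(1, 2, 4)), 0.8, 0.1, 0.8062),
        fx_entry(phi(3), 0.1, -0.1, 0.1414),
        fx_entry(phi(4), 0.1, 0, 0.1)))
      M2 <- fx_cbba(f, list(
        fx_entry(phi(1:2), 0.1, 0, 0.1),
        fx_entry(phi(3), 0.1, -0.1, 0.1414),
        fx_entry(phi(4), 0.8, 0.1, 0.8062)))
      list(name = name, frame = f, cbbas = list(M1 = M1, M2 = M2),
           expected = list(
             K_mod = list(value = 0.2640, tol = 5e-4),
             bcd = list(value = 0.4380, tol = 5e-4)))
    },
    ex8_case3 = {
      f <- fod(phi(1:5))
      M1 <- fx_cbba(f, list(
        fx_entry(phi(1), 0.8, 0.1, 0.8062),
        fx_entry(phi(2:5), 0.2, -0.1, 0.2236)))
      M2 <- fx_cbba(f, list(fx_entry(phi(1:5), 1, 0, 1)))
      list(name = name, frame = f, cbbas = list(M1 = M1, M2 = M2),
           expected = list(
             K_mod = list(value = 0.0000, tol = 5e-4),
             bcd = list(value = 0.6062, tol = 5e-4)))
    },
    application = application_fixture()
  )
}

# Three disease patterns and one sample over the frame {y, n}, three
# attributes each.
application_fixture <- function() {
  f <- fod(c("y", "n"))
  ent <- function(re_y, im_y, m_y, re_n, im_n, m_n, re_b, im_b, m_b) {
    fx_cbba(f, list(fx_entry("y", re_y, im_y, m_y),
                    fx_entry("n", re_n, im_n, m_n),
                    fx_entry(c("y", "n"), re_b, im_b, m_b)))
  }
  patterns <- list(
    p1 = attributed_evidence("p1", list(
      a1 = ent(0.99, 0.01, 0.9901, 0, 0, 0, 0.01, -0.01, 0.0141),
      a2 = ent(0.8, 0.1, 0.8062, 0, 0, 0, 0.2, -0.1, 0.2236),
      a3 = ent(0.7, 0.1, 0.7071, 0.1, -0.05, 0.1118, 0.2, -0.05, 0.2062))),
    p2 = attributed_evidence("p2", list(
      a1 = ent(0.9, 0.1, 0.9055, 0.1, -0.1, 0.1414, 0, 0, 0),
      a2 = ent(0.99, 0.01, 0.9901, 0, 0, 0, 0.01, -0.01, 0.0141),
      a3 = ent(0.9, 0.1, 0.9055, 0, 0, 0, 0.1, -0.1, 0.1414))),
    p3 = attributed_evidence("p3", list(
      a1 = ent(0.6, 0.1, 0.6083, 0.2, -0.05, 0.2062, 0.2, -0.05, 0.2062),
      a2 = ent(0.8, 0.1, 0.8062, 0, 0, 0, 0.2, -0.1, 0.2236),
      a3 = ent(0.99, 0.01, 0.9901, 0, 0, 0, 0.01, -0.01, 0.0141))))
  sample <- attributed_evidence("s1", list(
    a1 = ent(0.5, 0.1, 0.5099, 0.3, -0.05, 0.3041, 0.2, -0.05, 0.2062),
    a2 = ent(0.6, 0.1, 0.6083, 0.2, -0.05, 0.2062, 0.2, -0.05, 0.2062),
    a3 = ent(0.8, 0.1, 0.8062, 0.1, -0.05, 0.1118, 0.1, -0.05, 0.1118)))
  list(
    name = "application",
    frame = f,
    cbbas = list(patterns = patterns, sample = sample,
                 weights = c(a1 = 0.3, a2 = 0.35, a3 = 0.35)),
    expected = list(
      bcd_uniform = list(value = c(p1 = 0.2157, p2 = 0.2337, p3 = 0.1525),
                         tol = 5e-4),
      bcd_weighted = list(value = c(p1 = 0.2065, p2 = 0.2303, p3 = 0.1551),
                          tol = 5e-4),
      chosen = list(value = "p3", tol = NA),
      ranking = list(value = c("p3", "p1", "p2"), tol = NA)))
}

#' Parametric CBBA pair on a 20-element frame
#'
#' Generates the pair used to study how the distance responds to a growing
#' hypothesis while the conflict coefficient stays blind to it. The first
#' CBBA has four focal elements on the 20-element frame
#' `{phi1, ..., phi20}`:
#' `{phi2,phi3,phi4}` with mass `0.05 + alpha*1i`, `{phi7}` with mass
#' `0.05`, the full frame with mass `0.1`, and the growing hypothesis
#' `{phi1, ..., phi_subset_index}` with mass `0.8 - alpha*1i` (masses on a
#' repeated subset accumulate, which happens when the growing hypothesis
#' reaches the full frame). The second CBBA is certain evidence on
#' `{phi1, ..., phi5}`. With `alpha = 0` both reduce to classical BBAs, and
#' the betting-commitment distance equals the classical difBetP.
#'
#' @param alpha Imaginary amplitude; admissible while
#'   `0.8^2 + alpha^2 <= 1`.
#' @param subset_index Integer in `1:20`: the growing hypothesis is the
#'   first `subset_index` frame elements.
#' @return A list with `M1` and `M2` (`cbba` objects).
#' @export
cet_example7 <- function(alpha, subset_index) {
  if (0.8^2 + alpha^2 > 1 + 1e-12) {
    stop(sprintf(
      "alpha = %g inadmissible: 0.8^2 + alpha^2 = %.4f exceeds 1",
      alpha, 0.8^2 + alpha^2), call. = FALSE)
  }
  subset_index <- as.integer(subset_index)
  stopifnot(length(subset_index) == 1L, subset_index >= 1L,
            subset_index <= 20L)
  f <- fod(phi(1:20))
  subsets <- list(phi(2:4), phi(7), phi(1:20), phi(seq_len(subset_index)))
  mass <- c(complex(real = 0.05, imaginary = alpha), 0.05 + 0i, 0.1 + 0i,
            complex(real = 0.8, imaginary = -alpha))
  # accumulate masses on repeated subsets (growing hypothesis = full frame)
  keys <- vapply(subsets, function(s) subset_key(f, s), numeric(1))
  agg <- rowsum(cbind(Re(mass), Im(mass)), group = keys)
  ukeys <- as.numeric(rownames(agg))
  M1 <- cbba(f, lapply(ukeys, function(k) key_members(f, k)),
             complex(real = agg[, 1], imaginary = agg[, 2]))
  M2 <- cbba(f, list(phi(1:5)), 1 + 0i)
  list(M1 = M1, M2 = M2)
}

#' Random CBBA generator
#'
#' Draws a reproducible random CBBA for property testing: `n_focal`
#' distinct non-empty subsets are sampled, real parts are drawn positive
#' and rescaled to sum to 1, imaginary parts are drawn uniformly in
#' `[-imag_scale, imag_scale]` and shifted to sum to 0, and the draw is
#' rejected and repeated until every magnitude is at most 1. With
#' `imag_scale = 0` the result is a classical BBA. The caller's random
#' number generator state is left untouched.
#'
#' @param frame A [fod()] object.
#' @param n_focal Number of focal elements, in `1:(2^n - 1)`.
#' @param imag_scale Half-width of the imaginary-part distribution, in
#'   `[0, 0.5]`.
#' @param seed Integer seed; the same seed always yields the same CBBA.
#' @return A `cbba` object passing [validate_cbba()] at `1e-9`.
#' @export
random_cbba <- function(frame, n_focal, imag_scale = 0.2, seed) {
  stopifnot(inherits(frame, "fod"))
  n_subsets <- 2^frame$n - 1
  if (n_focal < 1 || n_focal > n_subsets) {
    stop(sprintf("n_focal must be in 1..%d", n_subsets), call. = FALSE)
  }
  if (imag_scale < 0 || imag_scale > 0.5) {
    stop("imag_scale must be in [0, 0.5]", call. = FALSE)
  }
  with_preserved_seed(seed, {
    keys <- sample.int(n_subsets, n_focal)
    repeat {
      re <- stats::runif(n_focal)
      re <- re / sum(re)
      im <- if (imag_scale == 0) {
        rep(0, n_focal)
      } else {
        y <- stats::runif(n_focal, -imag_scale, imag_scale)
        y - mean(y)
      }
      if (all(re^2 + im^2 <= 1)) break
    }
    cbba(frame, lapply(keys, function(k) key_members(frame, k)),
         complex(real = re, imaginary = im))
  })
}

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
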