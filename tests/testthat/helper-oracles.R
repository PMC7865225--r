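# Independent brute-force oracles. These deliberately avoid the package's
# internal shortcuts (bitmask accumulation, subset-sum doubling, closed
# forms): they loop over explicit member vectors so that agreement with the
# implementation is a genuine cross-check.

# all non-empty subsets of a label vector, as a list of character vectors
oracle_subsets <- function(elements) {
  n <- length(elements)
  out <- list()
  for (k in seq_len(2^n - 1)) {
    keep <- as.logical(bitwAnd(k %/% 2^(seq_len(n) - 1), 1))
    out[[length(out) + 1]] <- elements[keep]
  }
  out
}

# masses of a cbba as (list of member vectors, complex vector)
oracle_masses <- function(M) {
  subs <- lapply(M$keys, function(k) {
    n <- M$frame$n
    M$frame$elements[as.logical(bitwAnd(as.integer(k) %/% 2^(seq_len(n) - 1), 1))]
  })
  list(subsets = subs, mass = M$mass)
}

# classical Dempster combination by exhaustive pair enumeration over the
# stored entries, in real arithmetic; returns mass lookup by subset label
oracle_dempster <- function(m1, m2) {
  a <- oracle_masses(m1); b <- oracle_masses(m2)
  key <- function(s) paste(sort(s), collapse = "|")
  acc <- list(); conflict <- 0
  for (i in seq_along(a$subsets)) for (j in seq_along(b$subsets)) {
    inter <- intersect(a$subsets[[i]], b$subsets[[j]])
    prod <- Re(a$mass[i]) * Re(b$mass[j])
    if (length(inter) == 0) {
      conflict <- conflict + prod
    } else {
      k <- key(inter)
      acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + prod
    }
  }
  list(mass = lapply(acc, function(v) v / (1 - conflict)),
       conflict = conflict)
}

# complex pignistic value of one subset straight from the definition:
# each member singleton collects mass/|focal| from every focal set
# containing it, and the subset value is the sum over its members
oracle_cpt <- function(M, subset) {
  m <- oracle_masses(M)
  total <- 0 + 0i
  for (el in subset) {
    for (i in seq_along(m$subsets)) {
      if (Mod(m$mass[i]) > 0 && el %in% m$subsets[[i]]) {
        total <- total + m$mass[i] / length(m$subsets[[i]])
      }
    }
  }
  total
}

# betting-commitment distance by explicit enumeration of every subset
oracle_bcd <- function(Mu, Mv) {
  subs <- oracle_subsets(Mu$frame$elements)
  max(vapply(subs, function(s)
    abs(Mod(oracle_cpt(Mu, s)) - Mod(oracle_cpt(Mv, s))), numeric(1)))
}

# classical difBetP by explicit enumeration, all-real arithmetic
oracle_difbetp <- function(mu, mv) {
  subs <- oracle_subsets(mu$frame$elements)
  betp <- function(M, s) Re(oracle_cpt(M, s))
  max(vapply(subs, function(s) abs(betp(mu, s) - betp(mv, s)), numeric(1)))
}

# random classical BBA built without random_cbba's machinery
oracle_random_bba <- function(frame, seed) {
  set.seed(seed)
  subs <- oracle_subsets(frame$elements)
  k <- sample(2:min(4, length(subs)), 1)
  pick <- sample(seq_along(subs), k)
  w <- runif(k); w <- w / sum(w)
  cbba(frame, subs[pick], complex(real = w, imaginary = 0))
}
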