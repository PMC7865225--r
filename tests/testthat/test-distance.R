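test_that("bcd reproduces the three reference case distances", {
  expect_equal(bcd(cet_example("ex8_case1")$cbbas$M1,
                   cet_example("ex8_case1")$cbbas$M2), 0.7062,
               tolerance = 5e-4)
  expect_equal(bcd(cet_example("ex8_case2")$cbbas$M1,
                   cet_example("ex8_case2")$cbbas$M2), 0.4380,
               tolerance = 5e-4)
  expect_equal(bcd(cet_example("ex8_case3")$cbbas$M1,
                   cet_example("ex8_case3")$cbbas$M2), 0.6062,
               tolerance = 5e-4)
  ex2 <- cet_example("ex2")
  expect_equal(bcd(ex2$cbbas$M1, ex2$cbbas$M2), 0)
})

test_that("bcd satisfies the pseudo-metric axioms on random CBBAs", {
  f <- fod(letters[1:3])
  for (seed in 1:500) {
    Mu <- random_cbba(f, n_focal = 4, imag_scale = 0.3, seed = seed)
    Mv <- random_cbba(f, n_focal = 5, imag_scale = 0.3, seed = seed + 10000)
    duv <- bcd(Mu, Mv)
    expect_gte(duv, 0)                                   # non-negativity
    expect_equal(duv, bcd(Mv, Mu), tolerance = 1e-12)    # symmetry
    if (seed <= 250) {
      Mw <- random_cbba(f, n_focal = 3, imag_scale = 0.3, seed = seed + 20000)
      duw <- bcd(Mu, Mw); dvw <- bcd(Mv, Mw)
      expect_lte(duw, duv + dvw + 1e-12)                 # triangle
    }
  }
  # identity of a CBBA with itself, exactly
  expect_identical(bcd(cet_example("ex1")$cbbas$M1,
                       cet_example("ex1")$cbbas$M1), 0)
})

test_that("bcd equals the naive per-subset oracle on small frames", {
  for (n in 2:4) {
    f <- fod(letters[seq_len(n)])
    for (seed in 1:15) {
      Mu <- random_cbba(f, n_focal = min(4, 2^n - 1), imag_scale = 0.3,
                        seed = seed)
      Mv <- random_cbba(f, n_focal = min(3, 2^n - 1), imag_scale = 0.3,
                        seed = seed + 5000)
      expect_equal(bcd(Mu, Mv), oracle_bcd(Mu, Mv), tolerance = 1e-12)
    }
  }
})

test_that("bcd reduces to difBetP on classical inputs", {
  f <- fod(letters[1:3])
  for (seed in 1:100) {
    mu <- random_cbba(f, n_focal = 4, imag_scale = 0, seed = seed)
    mv <- random_cbba(f, n_focal = 5, imag_scale = 0, seed = seed + 7000)
    expect_equal(bcd(mu, mv), difbetp(mu, mv), tolerance = 1e-12)
    expect_equal(difbetp(mu, mv), oracle_difbetp(mu, mv), tolerance = 1e-12)
  }
  expect_error(difbetp(cet_example("ex1")$cbbas$M1,
                       cet_example("ex1")$cbbas$M2), "classical")
  ex3 <- cet_example("ex3")
  expect_equal(difbetp(ex3$cbbas$M1, ex3$cbbas$M2), 0)
})

test_that("the parametric 20-element pair degenerates cleanly at alpha = 0", {
  for (i in 1:20) {
    pair <- cet_example7(0, i)
    expect_true(is_classical(pair$M1))
    expect_equal(bcd(pair$M1, pair$M2), difbetp(pair$M1, pair$M2),
                 tolerance = 1e-12)
  }
  expect_s3_class(cet_example7(0.5, 1)$M1, "cbba")
  expect_error(cet_example7(0.7, 1), "inadmissible")
})

test_that("pignistically equivalent but distinct BBAs are at distance zero", {
  # the known counterexample to strict nondegeneracy: a uniform split of a
  # two-element focal set and the focal set itself share every betting
  # commitment, so bcd = 0 although the mass functions differ
  f <- fod(c("a", "b"))
  m1 <- cbba(f, list("a", "b"), c(0.5, 0.5))
  m2 <- cbba(f, list(c("a", "b")), 1)
  expect_false(isTRUE(all.equal(m1, m2)))
  expect_equal(bcd(m1, m2), 0)
})

test_that("multi-attribute distances reproduce the diagnosis table", {
  app <- cet_example("application")
  s1 <- app$cbbas$sample
  p <- app$cbbas$patterns
  expect_equal(attribute_distance(s1, p$p1), 0.2157, tolerance = 5e-4)
  expect_equal(attribute_distance(s1, p$p2), 0.2337, tolerance = 5e-4)
  expect_equal(attribute_distance(s1, p$p3), 0.1525, tolerance = 5e-4)
  w <- app$cbbas$weights
  expect_equal(attribute_distance(s1, p$p1, w), 0.2065, tolerance = 5e-4)
  expect_equal(attribute_distance(s1, p$p2, w), 0.2303, tolerance = 5e-4)
  expect_equal(attribute_distance(s1, p$p3, w), 0.1551, tolerance = 5e-4)
  # uniform weighting is the explicit 1/eta average
  manual <- mean(vapply(names(s1$evidence), function(a)
    bcd(s1$evidence[[a]], p$p1$evidence[[a]]), numeric(1)))
  expect_equal(attribute_distance(s1, p$p1), manual, tolerance = 1e-12)
})

test_that("attribute and weight mismatches are rejected", {
  app <- cet_example("application")
  s1 <- app$cbbas$sample
  p1 <- app$cbbas$patterns$p1
  crippled <- attributed_evidence("p1x", p1$evidence[c("a1", "a2")])
  expect_error(attribute_distance(s1, crippled), "attribute sets differ")
  expect_error(attribute_distance(s1, p1, c(a1 = 0.3, a2 = 0.35, a3 = 0.4)),
               "sum to 1")
  expect_error(attribute_distance(s1, p1, c(x = 0.5, y = 0.25, z = 0.25)),
               "named by the attribute")
})
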