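test_that("conflict coefficient reproduces the reference pairs", {
  ex1 <- cet_example("ex1")
  expect_equal(conflict_coefficient(ex1$cbbas$M1, ex1$cbbas$M2)$modulus,
               1.0002, tolerance = 5e-4)
  ex2 <- cet_example("ex2")
  expect_equal(conflict_coefficient(ex2$cbbas$M1, ex2$cbbas$M2)$modulus, 0)
  ex3 <- cet_example("ex3")
  expect_equal(conflict_coefficient(ex3$cbbas$M1, ex3$cbbas$M2)$modulus, 0.75)
  # the vacuous CBBA conflicts with nothing
  vac <- vacuous_cbba(ex1$frame)
  expect_equal(conflict_coefficient(ex1$cbbas$M1, vac)$value, 0 + 0i)
  expect_error(conflict_coefficient(ex1$cbbas$M1, cet_example("ex2")$cbbas$M1),
               "frame")
})

test_that("conflict coefficient is symmetric in its arguments", {
  f <- fod(letters[1:4])
  for (seed in 1:25) {
    Mu <- random_cbba(f, n_focal = 5, imag_scale = 0.2, seed = seed)
    Mv <- random_cbba(f, n_focal = 4, imag_scale = 0.2, seed = seed + 1000)
    expect_equal(conflict_coefficient(Mu, Mv)$value,
                 conflict_coefficient(Mv, Mu)$value, tolerance = 1e-14)
  }
})

test_that("the vacuous CBBA is the neutral element of combination", {
  for (nm in c("ex1", "ex2", "ex8_case3")) {
    M <- cet_example(nm)$cbbas$M1
    fused <- combine_cbba(M, vacuous_cbba(M$frame))
    expect_true(isTRUE(all.equal(fused, M, tolerance = 1e-12)))
  }
})

test_that("combination agrees with the exhaustive pair-product oracle", {
  ex2 <- cet_example("ex2")
  fused <- combine_cbba(ex2$cbbas$M1, ex2$cbbas$M2)
  # exhaustive enumeration of the 9 focal-pair products, by hand
  m <- list("phi1" = 0.4 + 0.1i, "phi1|phi2" = 0.4 - 0.1i,
            "phi1|phi2|phi3" = 0.2 + 0i)
  key <- function(s) paste(sort(s), collapse = "|")
  acc <- list()
  for (a in names(m)) for (b in names(m)) {
    inter <- key(intersect(strsplit(a, "|", fixed = TRUE)[[1]],
                           strsplit(b, "|", fixed = TRUE)[[1]]))
    acc[[inter]] <- (if (is.null(acc[[inter]])) 0 else acc[[inter]]) +
      m[[a]] * m[[b]]
  }
  for (lab in names(acc)) {
    expect_equal(cbba_mass(fused, strsplit(lab, "|", fixed = TRUE)[[1]]),
                 acc[[lab]], tolerance = 1e-12)
  }
  expect_equal(sum(fused$mass), 1 + 0i, tolerance = 1e-12)
})

test_that("classical inputs reduce to the classical Dempster rule", {
  f <- fod(letters[1:4])
  for (seed in 1:20) {
    m1 <- random_cbba(f, n_focal = 4, imag_scale = 0, seed = seed)
    m2 <- random_cbba(f, n_focal = 4, imag_scale = 0, seed = seed + 500)
    ref <- oracle_dempster(m1, m2)
    if (abs(1 - ref$conflict) < 1e-9) next
    fused <- combine_cbba(m1, m2)
    expect_true(all(abs(Im(fused$mass)) <= 1e-12))
    for (lab in names(ref$mass)) {
      expect_equal(Re(cbba_mass(fused, strsplit(lab, "|", fixed = TRUE)[[1]])),
                   ref$mass[[lab]], tolerance = 1e-10)
    }
  }
  # the uniform singleton pair: K = 0.75, fused is again uniform
  ex3 <- cet_example("ex3")
  fused <- combine_cbba(ex3$cbbas$M1, ex3$cbbas$M2)
  expect_equal(unname(Re(fused$mass)), rep(0.25, 4), tolerance = 1e-12)
})

test_that("combination is commutative and associative on random CBBAs", {
  f <- fod(letters[1:3])
  n_assoc <- 0
  for (seed in 1:200) {
    Mu <- random_cbba(f, n_focal = 4, imag_scale = 0.2, seed = seed)
    Mv <- random_cbba(f, n_focal = 5, imag_scale = 0.2, seed = seed + 2000)
    expect_true(isTRUE(all.equal(combine_cbba(Mu, Mv), combine_cbba(Mv, Mu),
                                 tolerance = 1e-12)))
    if (seed <= 100) {
      Mw <- random_cbba(f, n_focal = 3, imag_scale = 0.2, seed = seed + 4000)
      left <- tryCatch(combine_cbba(combine_cbba(Mu, Mv), Mw),
                       error = function(e) NULL)
      right <- tryCatch(combine_cbba(Mu, combine_cbba(Mv, Mw)),
                        error = function(e) NULL)
      if (!is.null(left) && !is.null(right)) {
        n_assoc <- n_assoc + 1
        expect_true(isTRUE(all.equal(left, right, tolerance = 1e-9)))
      }
    }
  }
  expect_gt(n_assoc, 50)  # the total-conflict guard should be rare here
})

test_that("fused masses conserve the unit complex sum", {
  f <- fod(letters[1:4])
  for (seed in 1:50) {
    Mu <- random_cbba(f, n_focal = 6, imag_scale = 0.3, seed = seed)
    Mv <- random_cbba(f, n_focal = 6, imag_scale = 0.3, seed = seed + 3000)
    fused <- tryCatch(combine_cbba(Mu, Mv), error = function(e) NULL)
    if (is.null(fused)) next
    expect_lt(Mod(sum(fused$mass) - (1 + 0i)), 1e-9)
  }
})

test_that("total conflict is refused with a helpful error", {
  f <- fod(c("a", "b"))
  m1 <- cbba(f, list("a"), 1)
  m2 <- cbba(f, list("b"), 1)
  expect_error(combine_cbba(m1, m2), "total conflict")
})
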