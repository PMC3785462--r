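test_that("the Pearson statistic matches hand-computed values", {
  expect_equal(chisq_stat(rbind(c(5, 5), c(5, 5))), 0)
  expect_equal(chisq_stat(rbind(c(10, 0), c(0, 10))), 20)
  # invariance under row swap and column permutation
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(rpois(8, 6) + 1L, 2, 4)
    s <- chisq_stat(m)
    expect_equal(chisq_stat(m[2:1, ]), s)
    expect_equal(chisq_stat(m[, sample(4)]), s)
  }
})

test_that("degenerate tables are handled: zero columns drop, zero rows err", {
  expect_warning(s <- chisq_stat(rbind(c(5, 5, 0), c(9, 1, 0))),
                 "all-zero column")
  expect_equal(s, chisq_stat(rbind(c(5, 5), c(9, 1))))
  expect_warning(r <- pvalue_asymptotic(rbind(c(5, 5, 0), c(9, 1, 0))))
  expect_equal(r$df, 1)  # df follows the retained columns
  expect_error(chisq_stat(rbind(c(0, 0), c(3, 4))), "zero row")
})

test_that("asymptotic p-values are the chi-square upper tail", {
  expect_equal(pvalue_asymptotic(rbind(c(5, 5), c(5, 5)))$p_value, 1)
  r <- pvalue_asymptotic(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$p_value, stats::pchisq(20, 1, lower.tail = FALSE))
  expect_equal(r$p_value, 7.74e-6, tolerance = 1e-3)
})

test_that("Cochran's rule flags sparse expected counts", {
  expect_true(cochran_rule_ok(rbind(c(50, 50), c(50, 50))))
  # first column expectation exactly 1; half the cells below 5
  expect_false(cochran_rule_ok(rbind(c(1, 99), c(1, 99))))
  # an expected cell of 0.5 violates the first clause
  expect_false(cochran_rule_ok(rbind(c(1, 99), c(0, 100))))
})

test_that("permutation p-values converge to the enumerated exact value", {
  m <- count_table(rbind(c(2, 0), c(0, 2)))
  p_exact <- exact_perm_p(unclass(m))
  expect_equal(p_exact, 1 / 3, tolerance = 1e-12)
  set.seed(22)
  p_mc <- pvalue_permutation(m, B = 1e5)$p_value
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 1e5))
  # a zero statistic means every resample ties or exceeds: p = 1
  set.seed(23)
  expect_equal(pvalue_permutation(rbind(c(5, 5), c(5, 5)), B = 500)$p_value,
               1)
  # determinism under a fixed seed
  tab <- count_table(rbind(c(8, 2, 5), c(3, 7, 5)))
  set.seed(24); a <- pvalue_permutation(tab, B = 2000)$p_value
  set.seed(24); b <- pvalue_permutation(tab, B = 2000)$p_value
  expect_identical(a, b)
})

test_that("Fisher MC p-values converge to the enumerated exact value", {
  m <- count_table(rbind(c(3, 1), c(1, 3)))
  p_exact <- exact_fisher_p(unclass(m))
  expect_equal(p_exact, 34 / 70, tolerance = 1e-12)
  # cross-check the oracle itself against the standard exact test
  expect_equal(p_exact, stats::fisher.test(unclass(m))$p.value,
               tolerance = 1e-12)
  set.seed(25)
  p_mc <- pvalue_fisher_mc(m, B = 1e5)$p_value
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 1e5))
  # the modal (perfectly balanced) table is never beaten: p = 1
  set.seed(26)
  expect_equal(
    pvalue_fisher_mc(rbind(c(10, 10), c(10, 10)), B = 500)$p_value, 1)
})

test_that("margin-fixed resamples preserve both margins exactly", {
  set.seed(27)
  for (rep in 1:5) {
    k <- sample(2:6, 1)
    m <- matrix(rpois(2 * k, 8) + 1L, 2, k)
    draws <- sample_margin_fixed(m, 200)
    for (d in draws) {
      expect_identical(rowSums(d), rowSums(m))
      expect_identical(colSums(d), colSums(m))
    }
  }
})

test_that("the margin-fixed sampler matches the hypergeometric law", {
  # first-cell distribution vs the exact pmf, with r2dtable as a second,
  # independent sampler of the same law
  m <- rbind(c(4L, 4L), c(5L, 3L))
  set.seed(28)
  ours <- vapply(sample_margin_fixed(m, 20000), function(t) t[1, 1],
                 integer(1))
  ref <- vapply(r2dtable(20000, rowSums(m), colSums(m)),
                function(t) t[1, 1], integer(1))
  a <- 1:8  # support of the first cell given these margins
  pmf <- stats::dhyper(a, colSums(m)[1], colSums(m)[2], rowSums(m)[1])
  sup <- a[pmf > 0]
  gof_ours <- suppressWarnings(stats::chisq.test(
    tabulate(ours + 1L, 9)[sup + 1L], p = pmf[sup]))
  gof_ref <- suppressWarnings(stats::chisq.test(
    tabulate(ref + 1L, 9)[sup + 1L], p = pmf[sup]))
  expect_gt(gof_ours$p.value, 1e-4)
  expect_gt(gof_ref$p.value, 1e-4)
})

test_that("permutation p agrees with chisq.test's simulated p", {
  tab <- rbind(c(30, 25, 12, 8), c(20, 30, 15, 5))
  B <- 20000
  set.seed(29)
  ours <- pvalue_permutation(tab, B = B)$p_value
  ref <- suppressWarnings(
    stats::chisq.test(tab, simulate.p.value = TRUE, B = B))$p.value
  joint_se <- sqrt(2 * ref * (1 - ref) / B)
  expect_lt(abs(ours - ref), 4 * joint_se)
})

test_that("asymptotic and permutation calibrations agree at large N", {
  sp <- euro11_spectrum()
  set.seed(30)
  cf <- build_case_frequencies(sp, effect_spec("J", deviation = 0.35))
  for (rep in 1:3) {
    tab <- simulate_table(sp$freqs, cf, 1000, 1000)
    pa <- pvalue_asymptotic(tab)$p_value
    pp <- pvalue_permutation(tab, B = 20000)$p_value
    expect_lt(abs(pa - pp), 0.02)
  }
})
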