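test_that("minimum cases under a ratio are minimal and match closed form", {
  set.seed(501)
  for (rep in 1:20) {
    p0 <- stats::runif(1, 0.05, 0.35)
    delta <- stats::runif(1, 0.3, 1)
    k <- sample(4:16, 1)
    r <- sample(c(1, 2, 3), 1)
    star <- stats::runif(1, 3, 14)
    eff <- effect_spec(1, deviation = delta)
    res <- min_cases_given_ratio(star, r, p0, eff, k)
    n <- res$n_cases_min
    p1 <- p0 * (1 + delta)
    stat_at <- function(nc) n_sc_corrected(p0, p1, nc, floor(r * nc), k)
    expect_gte(stat_at(n), star)
    if (n > 1) expect_lt(stat_at(n - 1), star)
    # closed-form inversion agrees to within the integer boundary
    pbar <- (p0 + p1) / 2
    n_cf <- star * k^0.37 * pbar * (1 - pbar) * (1 + 1 / r) / (p1 - p0)^2
    expect_lte(abs(n - n_cf), 1 + 1 / r)  # floor() on controls adds slack
  }
})

test_that("more controls per case never increase the required cases", {
  eff <- effect_spec(1, deviation = 0.5)
  n1 <- min_cases_given_ratio(6.5, 1, 0.15, eff, 11)$n_cases_min
  n2 <- min_cases_given_ratio(6.5, 2, 0.15, eff, 11)$n_cases_min
  n4 <- min_cases_given_ratio(6.5, 4, 0.15, eff, 11)$n_cases_min
  expect_lte(n2, n1)
  expect_lte(n4, n2)
})

test_that("fixed-arm searches are minimal, mirrored, and flag ceilings", {
  eff <- effect_spec(1, deviation = 0.5)
  p0 <- 0.15; k <- 11; star <- 6.5
  p1 <- p0 * 1.5
  res <- min_controls_given_cases(star, 600, p0, eff, k)
  expect_true(res$feasible)
  expect_gte(n_sc_corrected(p0, p1, 600, res$n_controls_min, k), star)
  expect_lt(n_sc_corrected(p0, p1, 600, res$n_controls_min - 1, k), star)
  # mirrored problem returns the same count on the other arm
  mir <- min_cases_given_controls(star, 600, p0, eff, k)
  expect_identical(mir$n_cases_min, res$n_controls_min)
  # consistency with the ratio search at r = 1
  eq <- min_cases_given_ratio(star, 1, p0, eff, k)
  res_eq <- min_controls_given_cases(star, eq$n_cases_min, p0, eff, k)
  expect_lte(res_eq$n_controls_min, eq$n_cases_min + 1)
  # a small fixed case arm makes the target unreachable: result, not error
  inf <- min_controls_given_cases(star, 30, p0, eff, k)
  expect_false(inf$feasible)
  expect_lt(inf$limit, star)
  expect_equal(inf$limit,
               n_sc_corrected(p0, p1, 30, 10^9, k), tolerance = 1e-4)
})

test_that("designs from the inversion reach the target power", {
  cal <- default_calibration()
  star <- nsc_star(cal, 0.05, 0.80)
  sp <- euro11_spectrum()
  eff <- effect_spec("J", deviation = 1)
  res <- min_cases_given_ratio(star, 2, sp$freqs[3], eff, sp$k)
  d <- study_design(n_cases = res$n_cases_min,
                    n_controls = res$n_controls_min,
                    n_sim = 2000, seed = 502)
  est <- estimate_power(sp, eff, d)
  expect_gte(est$power, 0.80 - 0.03)
})

test_that("the minimum detectable effect inverts the sample-size search", {
  set.seed(503)
  for (rep in 1:10) {
    p0 <- stats::runif(1, 0.05, 0.3)
    k <- sample(4:16, 1)
    star <- stats::runif(1, 4, 12)
    n_ca <- sample(200:2000, 1)
    r <- sample(c(1, 2, 3), 1)
    me <- min_detectable_effect(star, n_ca, r * n_ca, p0, k)
    expect_true(me$feasible)
    expect_gt(me$or_min, 1)
    expect_equal(me$achieved, star, tolerance = 1e-6)
    # plugging the detected effect back reproduces the case arm
    back <- min_cases_given_ratio(star, r, p0,
                                  effect_spec(1, deviation = me$delta_min),
                                  k)
    expect_lte(abs(back$n_cases_min - n_ca), 1)
  }
})

test_that("detectable effects shrink with more controls, to a floor", {
  p0 <- 0.11; k <- 11; star <- 6.5; n_ca <- 400
  d1 <- min_detectable_effect(star, n_ca, n_ca, p0, k)$delta_min
  d4 <- min_detectable_effect(star, n_ca, 4 * n_ca, p0, k)$delta_min
  d64 <- min_detectable_effect(star, n_ca, 64 * n_ca, p0, k)$delta_min
  expect_lt(d4, d1)
  expect_lt(d64, d4)
  expect_gt(d64, 0)
  # enormous arms push the detectable odds ratio toward 1
  huge <- min_detectable_effect(star, 5e6, 5e6, p0, k)
  expect_lt(huge$or_min, 1.01)
  expect_gt(huge$or_min, 1)
  # an impossible target is reported, not thrown
  imp <- min_detectable_effect(50, 20, 20, p0, k)
  expect_false(imp$feasible)
  expect_lt(imp$limit, 50)
})
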