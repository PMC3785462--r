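test_that("euro11 fixture loads with renormalization warning", {
  path <- system.file("extdata", "euro11.csv", package = "haplopower")
  expect_warning(sp <- read_spectrum(path), "renormaliz")
  expect_s3_class(sp, "category_spectrum")
  expect_equal(sp$k, 11)
  expect_equal(sp$raw_sum, 1.10, tolerance = 1e-12)
  expect_equal(sum(sp$freqs), 1, tolerance = 1e-12)
  expect_equal(sp$labels[1], "H")
  expect_equal(sp$freqs[1], 0.41 / 1.10, tolerance = 1e-12)
})

test_that("already-normalized spectra load silently; uniform renormalizes", {
  expect_no_warning(sp <- category_spectrum(c(0.5, 0.5)))
  expect_equal(sp$freqs, c(0.5, 0.5))
  sp3 <- suppressWarnings(category_spectrum(c(0.2, 0.2, 0.2)))
  expect_equal(sp3$freqs, rep(1 / 3, 3), tolerance = 1e-15)
})

test_that("malformed spectra are rejected with the offending row named", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,freq", "A,0.5", "B,-0.1"), tmp)
  expect_error(read_spectrum(tmp), "'B'")
  writeLines(c("label,freq", "A,0.5", "B,oops"), tmp)
  expect_error(read_spectrum(tmp), "row 2")
  writeLines(c("label,freq", "A,1.0"), tmp)
  expect_error(read_spectrum(tmp), "at least 2")
  writeLines(c("name,value", "A,0.5", "B,0.5"), tmp)
  expect_error(read_spectrum(tmp), "label,freq")
})

test_that("case frequencies follow the proportional-redistribution rule", {
  sp <- toy_spectrum()
  cf <- build_case_frequencies(sp, effect_spec("a", deviation = 0.5))
  expect_equal(unname(cf), c(0.6, 0.2, 0.2), tolerance = 1e-12)
  # null effect leaves the spectrum untouched
  cf0 <- build_case_frequencies(sp, effect_spec(2, deviation = 0))
  expect_equal(unname(cf0), sp$freqs)
  # infeasible effect reports the admissible bound
  sp2 <- category_spectrum(c(0.6, 0.4))
  expect_error(build_case_frequencies(sp2, effect_spec(1, deviation = 1)),
               "maximum admissible")
})

test_that("case frequencies sum to one and are monotone in the deviation", {
  set.seed(401)
  for (rep in 1:25) {
    k <- sample(3:12, 1)
    f <- as.numeric(stats::rgamma(k, 2)); f <- f / sum(f)
    sp <- suppressWarnings(category_spectrum(f))
    i <- sample(k, 1)
    dmax <- 1 / f[i] - 1
    deltas <- sort(stats::runif(3, 0, dmax * 0.95))
    cfs <- lapply(deltas, function(d)
      build_case_frequencies(sp, effect_spec(i, deviation = d)))
    for (cf in cfs) expect_equal(sum(cf), 1, tolerance = 1e-12)
    risky <- vapply(cfs, `[[`, numeric(1), i)
    expect_true(all(diff(risky) > 0))
    for (j in setdiff(seq_len(k), i)) {
      nonrisky <- vapply(cfs, `[[`, numeric(1), j)
      expect_true(all(diff(nonrisky) < 0))
    }
  }
})

test_that("deviation, case frequency and odds ratio interconvert exactly", {
  expect_equal(effect_as_or(0.3, 0.3), 1)
  expect_equal(effect_as_or(0.11, 0.22), (0.22 / 0.78) / (0.11 / 0.89))
  expect_equal(effect_as_or(0.11, 0.22), 2.282, tolerance = 1e-3)
  set.seed(402)
  p0 <- stats::runif(200, 0.01, 0.95)
  p1 <- stats::runif(200, p0, 0.99)
  expect_equal(or_to_p1(effect_as_or(p0, p1), p0), p1, tolerance = 1e-12)
  # the three parameterizations give the same case frequencies
  sp <- toy_spectrum()
  p0j <- sp$freqs[2]
  delta <- 0.8
  p1j <- p0j * (1 + delta)
  via_delta <- build_case_frequencies(sp, effect_spec(2, deviation = delta))
  via_p1 <- build_case_frequencies(sp, effect_spec(2, case_freq = p1j))
  via_or <- build_case_frequencies(
    sp, effect_spec(2, odds_ratio = effect_as_or(p0j, p1j)))
  expect_equal(via_delta, via_p1, tolerance = 1e-12)
  expect_equal(via_delta, via_or, tolerance = 1e-12)
})

test_that("effect specification demands exactly one parameterization", {
  expect_error(effect_spec(1), "exactly one")
  expect_error(effect_spec(1, deviation = 1, odds_ratio = 2), "exactly one")
  expect_error(effect_spec(1, case_freq = 1.2), "\\(0, 1\\)")
  expect_error(effect_as_or(0, 0.5), "p0")
  expect_error(effect_as_or(0.5, 1), "p1")
})
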