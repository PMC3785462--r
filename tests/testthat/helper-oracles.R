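# Exhaustive-enumeration oracles for 2x2 tables under the fixed-margins
# (multivariate hypergeometric) null. Independent of the package's
# samplers: plain combinatorics on the hypergeometric pmf.

# All 2x2 tables with the margins of `m`; returns control-row first cells,
# their null probabilities, chi-square statistics and log-probabilities.
enumerate_2x2 <- function(m) {
  r <- rowSums(m); cs <- colSums(m); N <- sum(m)
  a_min <- max(0L, r[1L] - cs[2L])
  a_max <- min(r[1L], cs[1L])
  a <- a_min:a_max
  prob <- stats::dhyper(a, cs[1L], cs[2L], r[1L])
  stat <- vapply(a, function(ai) {
    tab <- rbind(c(ai, r[1L] - ai), c(cs[1L] - ai, cs[2L] - (r[1L] - ai)))
    e <- outer(r, cs) / N
    sum((tab - e)^2 / e)
  }, numeric(1))
  list(a = a, prob = prob, stat = stat, logprob = log(prob))
}

# Exact permutation p: null probability that the statistic is >= observed.
exact_perm_p <- function(m) {
  if (any(colSums(m) == 0)) return(1)  # one informative column only
  en <- enumerate_2x2(m)
  obs <- en$stat[match(m[1L, 1L], en$a)]
  min(1, sum(en$prob[en$stat >= obs - 1e-9]))
}

# Exact Fisher p: null probability of tables no more probable than observed.
exact_fisher_p <- function(m) {
  if (any(colSums(m) == 0)) return(1)
  en <- enumerate_2x2(m)
  obs <- en$prob[match(m[1L, 1L], en$a)]
  min(1, sum(en$prob[en$prob <= obs * (1 + 1e-9)]))
}

# Canonical form of a 2x2 table under row and column swaps (the p-values
# are invariant, so enumerating canonical representatives suffices).
canonical_2x2 <- function(m) {
  cands <- list(m, m[2:1, ], m[, 2:1], m[2:1, 2:1])
  keys <- vapply(cands, function(x) paste(x, collapse = ","),
                 character(1))
  cands[[order(keys)[1L]]]
}

# A small labelled spectrum for reuse in tests.
toy_spectrum <- function() category_spectrum(c(a = 0.4, b = 0.3, c = 0.3))
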