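#' Scaled noncentrality statistics for the risky category
#'
#' The squared standardized difference between the risky category's case
#' and control frequencies, the summary that maps designs of any shape
#' onto a single power curve:
#'
#' * `n_scaled(p0, p1, N)` for equal arms of size `N`:
#'   `N * (p1 - p0)^2 / (2 * pbar * (1 - pbar))` with
#'   `pbar = (p0 + p1) / 2` (pooled variance);
#' * `n_sc(p0, p1, n_cases, n_controls)` for unequal arms:
#'   `(p1 - p0)^2 / (pbar * (1 - pbar) * (1/n_cases + 1/n_controls))`,
#'   which reduces exactly to `n_scaled` at equal arms and is symmetric in
#'   the two arm sizes; as `n_controls` grows with `n_cases` fixed it
#'   converges to the finite ceiling
#'   `n_cases * (p1 - p0)^2 / (pbar * (1 - pbar))` — the algebraic reason
#'   power goes stationary when only controls are added;
#' * `n_sc_corrected()` divides by `n_categories^exponent`
#'   (default exponent 0.37, the empirical constant that collapses power
#'   curves across different numbers of categories onto one curve; 0.5
#'   fits better below 50% power and is exposed via `exponent`).
#'
#' For a 2x2 design, `n_scaled` equals the Pearson chi-square statistic of
#' the table of expected counts and its null distribution is chi-square
#' with one degree of freedom.
#'
#' @param p0 control frequency of the risky category, in (0, 1).
#' @param p1 case frequency of the risky category, in (0, 1).
#' @param N per-arm sample size (equal arms).
#' @return The scaled statistic (non-negative scalar; vectorized over its
#'   arguments).
#' @examples
#' n_scaled(0.11, 0.22, 500)
#' n_sc(0.11, 0.22, 500, 1500)
#' n_sc_corrected(0.11, 0.22, 500, 1500, n_categories = 11)
#' @export
n_scaled <- function(p0, p1, N) {
  check_freq(p0, "p0"); check_freq(p1, "p1")
  if (any(N < 1)) stop("N must be >= 1")
  pbar <- (p0 + p1) / 2
  N * (p1 - p0)^2 / (2 * pbar * (1 - pbar))
}

#' @rdname n_scaled
#' @param n_cases,n_controls arm sizes (>= 1).
#' @export
n_sc <- function(p0, p1, n_cases, n_controls) {
  check_freq(p0, "p0"); check_freq(p1, "p1")
  if (any(n_cases < 1) || any(n_controls < 1))
    stop("both arm sizes must be >= 1")
  pbar <- (p0 + p1) / 2
  (p1 - p0)^2 / (pbar * (1 - pbar) * (1 / n_cases + 1 / n_controls))
}

#' @rdname n_scaled
#' @param n_categories number of marker categories (k >= 2).
#' @param exponent the collapse exponent (default 0.37).
#' @export
n_sc_corrected <- function(p0, p1, n_cases, n_controls, n_categories,
                           exponent = 0.37) {
  if (any(n_categories < 2)) stop("n_categories must be >= 2")
  n_sc(p0, p1, n_cases, n_controls) / n_categories^exponent
}

#' Closed-form power for a 2x2 design with equal arms
#'
#' Two-sided arcsine-transformation approximation: with
#' `phi_i = 2 * asin(sqrt(p_i))` and `D = |phi1 - phi0|`, power is
#' `pnorm(D * sqrt(N/2) - z) + pnorm(-D * sqrt(N/2) - z)` where `z` is the
#' upper `alpha/2` normal quantile. Both tails are kept so the null
#' (`p1 = p0`) returns exactly `alpha`.
#'
#' @inheritParams n_scaled
#' @param alpha significance level, strictly in (0, 1).
#' @return Power in (0, 1); vectorized.
#' @examples
#' power_arcsine_2x2(0.11, 0.22, N = 500, alpha = 0.05)
#' @export
power_arcsine_2x2 <- function(p0, p1, N, alpha = 0.05) {
  check_freq(p0, "p0"); check_freq(p1, "p1")
  if (any(N < 1)) stop("N must be >= 1")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  d <- abs(2 * asin(sqrt(p1)) - 2 * asin(sqrt(p0)))
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(d * sqrt(N / 2) - z) + stats::pnorm(-d * sqrt(N / 2) - z)
}
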