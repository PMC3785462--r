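# Inverse design problems: all are driven by the requirement that the
# corrected scaled statistic of the design reaches the calibrated
# threshold n_sc_star(alpha, beta) (see calibrate_nsc / nsc_star).

sample_size_result <- function(n_cases_min = NA_integer_,
                               n_controls_min = NA_integer_,
                               feasible = TRUE, ratio = NA_real_,
                               achieved = NA_real_, limit = NA_real_,
                               n_sc_star = NA_real_) {
  structure(list(n_cases_min = n_cases_min,
                 n_controls_min = n_controls_min, feasible = feasible,
                 ratio = ratio, achieved = achieved, limit = limit,
                 n_sc_star = n_sc_star),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf(
      "Minimum design: %s cases, %s controls (achieved statistic %.3f >= threshold %.3f)\n",
      x$n_cases_min, x$n_controls_min, x$achieved, x$n_sc_star))
  } else {
    cat(sprintf(
      "Infeasible: even with unlimited controls the statistic is capped at %.3f < threshold %.3f\n",
      x$limit, x$n_sc_star))
  }
  invisible(x)
}

# Corrected statistic of a candidate design; shared by the searches.
design_stat <- function(p0, p1, n_cases, n_controls, n_categories,
                        exponent) {
  n_sc_corrected(p0, p1, n_cases, n_controls, n_categories, exponent)
}

#' Minimum sample sizes reaching a calibrated power threshold
#'
#' Three inverse problems, all asking for the smallest integer design
#' whose corrected scaled statistic ([n_sc_corrected()]) reaches the
#' threshold `n_sc_star` (obtained from a calibration via [nsc_star()]):
#'
#' * `min_cases_given_ratio()`: smallest number of cases `N` under a fixed
#'   control-case ratio `r` (controls = `floor(r * N)`);
#' * `min_controls_given_cases()`: smallest number of controls for a fixed
#'   case arm — may be infeasible, because with `n_cases` fixed the
#'   statistic is capped at a finite ceiling no number of controls can
#'   exceed;
#' * `min_cases_given_controls()`: the mirrored problem.
#'
#' Minimality is the contract: the bound holds at the returned size and
#' fails one unit below. Infeasibility is a result state (`feasible =
#' FALSE` with the limiting achievable statistic), not an error.
#'
#' @param n_sc_star threshold value of the corrected statistic.
#' @param ratio control-case ratio r > 0.
#' @param p0 control frequency of the risky category.
#' @param effect an [effect_spec()] (resolved against `p0`).
#' @param n_categories number of marker categories k >= 2.
#' @param exponent collapse exponent (default 0.37).
#' @return A `sample_size_result`: `n_cases_min`, `n_controls_min`,
#'   `feasible`, `ratio`, `achieved` (corrected statistic at the returned
#'   design), `limit` (ceiling, when infeasible), `n_sc_star`.
#' @examples
#' eff <- effect_spec(1, deviation = 1)
#' min_cases_given_ratio(6.35, ratio = 2, p0 = 0.11, effect = eff,
#'                       n_categories = 11)
#' @export
min_cases_given_ratio <- function(n_sc_star, ratio, p0, effect,
                                  n_categories, exponent = 0.37) {
  if (ratio <= 0) stop("ratio must be > 0")
  p1 <- resolve_p1(p0, effect)
  if (p1 == p0) stop("a null effect has no finite minimum sample size")
  pbar <- (p0 + p1) / 2
  # closed-form warm start, exact up to the floor() on the control arm
  n0 <- n_sc_star * n_categories^exponent * pbar * (1 - pbar) *
    (1 + 1 / ratio) / (p1 - p0)^2
  n <- max(1L, as.integer(floor(n0)) - 2L)
  ok <- function(n) {
    n_co <- floor(ratio * n)
    n_co >= 1 &&
      design_stat(p0, p1, n, n_co, n_categories, exponent) >= n_sc_star
  }
  while (!ok(n)) n <- n + 1L
  while (n > 1L && ok(n - 1L)) n <- n - 1L
  sample_size_result(
    n_cases_min = n, n_controls_min = as.integer(floor(ratio * n)),
    feasible = TRUE, ratio = ratio,
    achieved = design_stat(p0, p1, n, floor(ratio * n), n_categories,
                           exponent),
    n_sc_star = n_sc_star)
}

#' @rdname min_cases_given_ratio
#' @param n_cases fixed number of cases.
#' @export
min_controls_given_cases <- function(n_sc_star, n_cases, p0, effect,
                                     n_categories, exponent = 0.37) {
  if (n_cases < 1) stop("n_cases must be >= 1")
  p1 <- resolve_p1(p0, effect)
  if (p1 == p0) stop("a null effect has no finite minimum sample size")
  pbar <- (p0 + p1) / 2
  # bound: 1/n_controls <= (p1-p0)^2 / (n_sc_star * k^e * pbar*(1-pbar))
  #        - 1/n_cases
  rhs <- (p1 - p0)^2 / (n_sc_star * n_categories^exponent *
                          pbar * (1 - pbar)) - 1 / n_cases
  limit <- (p1 - p0)^2 * n_cases / (pbar * (1 - pbar)) /
    n_categories^exponent
  if (rhs <= 0)
    return(sample_size_result(feasible = FALSE, limit = limit,
                              n_sc_star = n_sc_star,
                              ratio = NA_real_))
  n_co <- max(1L, as.integer(ceiling(1 / rhs)) - 2L)
  ok <- function(n_co)
    design_stat(p0, p1, n_cases, n_co, n_categories, exponent) >=
      n_sc_star
  while (!ok(n_co)) n_co <- n_co + 1L
  while (n_co > 1L && ok(n_co - 1L)) n_co <- n_co - 1L
  sample_size_result(
    n_cases_min = as.integer(n_cases), n_controls_min = n_co,
    feasible = TRUE, ratio = n_co / n_cases,
    achieved = design_stat(p0, p1, n_cases, n_co, n_categories, exponent),
    limit = limit, n_sc_star = n_sc_star)
}

#' @rdname min_cases_given_ratio
#' @param n_controls fixed number of controls.
#' @export
min_cases_given_controls <- function(n_sc_star, n_controls, p0, effect,
                                     n_categories, exponent = 0.37) {
  # n_sc is symmetric in the two arm sizes, so reuse the mirrored search
  out <- min_controls_given_cases(n_sc_star, n_controls, p0, effect,
                                  n_categories, exponent)
  if (!out$feasible) return(out)
  sample_size_result(
    n_cases_min = out$n_controls_min,
    n_controls_min = as.integer(n_controls), feasible = TRUE,
    ratio = n_controls / out$n_controls_min, achieved = out$achieved,
    limit = out$limit, n_sc_star = out$n_sc_star)
}

#' Minimum detectable effect for a fixed design
#'
#' Finds the smallest relative deviation `delta > 0` of the risky
#' category whose corrected scaled statistic reaches `n_sc_star`, by
#' bisection on the monotone map delta -> statistic (relative tolerance
#' 1e-10), subject to the feasibility constraint `p1 = p0 (1 + delta) <
#' 1`. Reports the deviation, the implied case frequency and the matching
#' minimum detectable odds ratio; when even `p1 -> 1` cannot reach the
#' threshold the result is flagged infeasible with the supremum of the
#' achievable statistic.
#'
#' @inheritParams min_cases_given_ratio
#' @param n_cases,n_controls arm sizes of the fixed design.
#' @return A list of class `min_effect_result`: `feasible`, `delta_min`,
#'   `p1_min`, `or_min`, `achieved`, `limit`, `n_sc_star`.
#' @examples
#' min_detectable_effect(6.35, n_cases = 500, n_controls = 1000,
#'                       p0 = 0.11, n_categories = 11)
#' @export
min_detectable_effect <- function(n_sc_star, n_cases, n_controls, p0,
                                  n_categories, exponent = 0.37) {
  check_freq(p0, "p0")
  if (n_cases < 1 || n_controls < 1) stop("both arms must be >= 1")
  f <- function(delta)
    design_stat(p0, p0 * (1 + delta), n_cases, n_controls, n_categories,
                exponent) - n_sc_star
  delta_max <- 1 / p0 - 1
  hi <- delta_max * (1 - 1e-9)
  if (f(hi) < 0)
    return(structure(list(feasible = FALSE, delta_min = NA_real_,
                          p1_min = NA_real_, or_min = NA_real_,
                          achieved = NA_real_,
                          limit = f(hi) + n_sc_star,
                          n_sc_star = n_sc_star),
                     class = "min_effect_result"))
  lo <- 0
  while ((hi - lo) > 1e-10 * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  delta <- hi
  p1 <- p0 * (1 + delta)
  structure(list(feasible = TRUE, delta_min = delta, p1_min = p1,
                 or_min = effect_as_or(p0, p1),
                 achieved = f(delta) + n_sc_star,
                 limit = NA_real_, n_sc_star = n_sc_star),
            class = "min_effect_result")
}

#' @export
print.min_effect_result <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf(
      "Minimum detectable effect: delta = %.4f (case frequency %.4f, OR = %.3f)\n",
      x$delta_min, x$p1_min, x$or_min))
  } else {
    cat(sprintf(
      "Infeasible: supremum of the achievable statistic is %.3f < threshold %.3f\n",
      x$limit, x$n_sc_star))
  }
  invisible(x)
}
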