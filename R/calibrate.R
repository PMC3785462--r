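#' Local-linear Gaussian-kernel regression (internal building block)
#'
#' Fits `y` on `x` by a local-linear estimator with a Gaussian kernel of
#' bandwidth `h`, evaluated at `xout`. Used to smooth Monte-Carlo power
#' against the corrected scaled statistic before inverting the curve.
#'
#' @param x,y data vectors.
#' @param h bandwidth (> 0), on the scale of `x`.
#' @param xout evaluation points.
#' @return Fitted values at `xout`.
#' @keywords internal
loclin_fit <- function(x, y, h, xout) {
  vapply(xout, function(x0) {
    u <- x - x0
    w <- stats::dnorm(u / h)
    s0 <- sum(w); s1 <- sum(w * u); s2 <- sum(w * u^2)
    if (s0 <= 0) return(NA_real_)  # no mass this far from any data
    t0 <- sum(w * y); t1 <- sum(w * u * y)
    den <- s0 * s2 - s1^2
    if (!is.finite(den) || den <= .Machine$double.eps * s0^2 * max(h, 1)^2)
      t0 / s0  # fall back to local constant in sparse regions
    else
      (s2 * t0 - s1 * t1) / den
  }, numeric(1))
}

# Leave-one-out CV score of the local-linear fit at bandwidth h.
loclin_loocv <- function(x, y, h) {
  n <- length(x)
  err <- vapply(seq_len(n), function(i) {
    yhat <- loclin_fit(x[-i], y[-i], h, x[i])
    y[i] - yhat
  }, numeric(1))
  mean(err^2)
}

# Pick the bandwidth minimizing LOO-CV over a log-spaced grid.
select_bandwidth <- function(x, y, bandwidths = NULL) {
  if (is.null(bandwidths)) {
    span <- diff(range(x))
    bandwidths <- exp(seq(log(span / 300), log(span / 3),
                          length.out = 15))
  }
  scores <- vapply(bandwidths, function(h) loclin_loocv(x, y, h),
                   numeric(1))
  scores[!is.finite(scores)] <- Inf  # h too small to cover every point
  list(bandwidth = bandwidths[which.min(scores)],
       grid = bandwidths, scores = scores)
}

#' Default scenario grid for the threshold calibration
#'
#' The factorial design-space the calibration simulates over: number of
#' categories 4/8/12/16/20, risky control frequency 0.30/0.15/0.05,
#' relative case increase 100%/50%/25%, cases 100/250/500/750/1000 and
#' control-case ratio 1/2/3, with the non-risky frequency mass split
#' uniformly over the remaining categories.
#'
#' @param n_categories,p0,deviation,n_cases,ratio factor levels.
#' @return A data frame with one row per scenario and columns
#'   `n_categories`, `p0`, `deviation`, `n_cases`, `ratio`, `n_controls`,
#'   `p1`.
#' @export
calibration_grid <- function(n_categories = c(4, 8, 12, 16, 20),
                             p0 = c(0.30, 0.15, 0.05),
                             deviation = c(1.0, 0.5, 0.25),
                             n_cases = c(100, 250, 500, 750, 1000),
                             ratio = c(1, 2, 3)) {
  g <- expand.grid(n_categories = n_categories, p0 = p0,
                   deviation = deviation, n_cases = n_cases, ratio = ratio,
                   KEEP.OUT.ATTRS = FALSE)
  g$n_controls <- floor(g$ratio * g$n_cases)
  g$p1 <- g$p0 * (1 + g$deviation)
  g
}

# Control/case frequency vectors for one scenario row: risky category
# first, remaining mass uniform over the other k - 1 categories.
scenario_freqs <- function(k, p0, p1) {
  ctrl <- c(p0, rep((1 - p0) / (k - 1), k - 1))
  case <- c(p1, rep((1 - p1) / (k - 1), k - 1))
  list(control = ctrl, case = case)
}

#' Calibrate the power threshold of the corrected scaled statistic
#'
#' Estimates, for each significance level `alpha`, the threshold value
#' `n_sc_star(alpha, beta)` of the corrected scaled statistic
#' ([n_sc_corrected()]) at which Monte-Carlo power reaches `beta`:
#' power is simulated for every scenario of `grid`, regressed on the
#' corrected statistic by local-linear Gaussian-kernel regression with
#' leave-one-out cross-validated bandwidth, the fitted curve is made
#' monotone by rearrangement, and inverted at each `beta`.
#'
#' @param alphas significance levels to calibrate.
#' @param betas target power values to invert at.
#' @param grid scenario data frame, see [calibration_grid()].
#' @param n_sim simulated tables per scenario.
#' @param method p-value calibration used inside the simulation
#'   (asymptotic by default: at the grid's sample sizes it agrees with the
#'   permutation calibration and is orders of magnitude faster).
#' @param n_perm resamples per table when `method` is not asymptotic.
#' @param exponent collapse exponent of the category-number correction.
#' @param seed integer RNG seed.
#' @param bandwidths optional bandwidth grid for cross-validation.
#' @return An object of class `nsc_calibration`: `table` (data frame
#'   `alpha`, `beta`, `n_sc_star`), `scenarios` (grid plus `x` =
#'   corrected statistic and one power column per alpha), `fits`
#'   (per-alpha bandwidth and curve), and the call settings.
#' @examples
#' \donttest{
#' cal <- calibrate_nsc(alphas = 0.05, betas = c(0.8, 0.9),
#'                      grid = calibration_grid(n_categories = c(4, 12)),
#'                      n_sim = 200, seed = 1)
#' cal$table
#' }
#' @export
calibrate_nsc <- function(alphas = c(0.10, 0.05, 0.01, 0.005, 0.001),
                          betas = seq(0.50, 0.95, by = 0.05),
                          grid = calibration_grid(), n_sim = 2000L,
                          method = c("asymptotic", "permutation",
                                     "fisher_mc"),
                          n_perm = 1000L, exponent = 0.37, seed = NULL,
                          bandwidths = NULL) {
  method <- match.arg(method)
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must lie in (0, 1)")
  if (any(betas <= 0 | betas >= 1)) stop("betas must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  x <- n_sc_corrected(grid$p0, grid$p1, grid$n_cases, grid$n_controls,
                      grid$n_categories, exponent)
  pow <- matrix(NA_real_, nrow(grid), length(alphas),
                dimnames = list(NULL, paste0("power_a", alphas)))
  for (i in seq_len(nrow(grid))) {
    f <- scenario_freqs(grid$n_categories[i], grid$p0[i], grid$p1[i])
    batch <- simulate_batch(f$control, f$case, grid$n_controls[i],
                            grid$n_cases[i], n_sim)
    p <- batch_pvalues(batch, method, n_perm)
    pow[i, ] <- vapply(alphas, function(a) mean(p < a), numeric(1))
  }
  scen <- cbind(grid, x = x, as.data.frame(pow))
  fits <- lapply(seq_along(alphas), function(j) {
    fit_power_curve(x, pow[, j], bandwidths)
  })
  names(fits) <- paste0("alpha_", alphas)
  tab <- do.call(rbind, lapply(seq_along(alphas), function(j) {
    data.frame(alpha = alphas[j], beta = betas,
               n_sc_star = invert_power_curve(fits[[j]], betas))
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, scenarios = scen, fits = fits,
                 alphas = alphas, betas = betas, exponent = exponent,
                 n_sim = as.integer(n_sim), method = method,
                 n_perm = as.integer(n_perm), seed = seed,
                 kernel = "gaussian", estimator = "local-linear",
                 bandwidth_rule = "leave-one-out CV"),
            class = "nsc_calibration")
}

# Fit one monotone power-vs-statistic curve: CV bandwidth, local-linear
# fit on a fine grid, monotone rearrangement (sorting the fitted values
# over the equispaced grid), clamped to [0, 1].
fit_power_curve <- function(x, power, bandwidths = NULL) {
  sel <- select_bandwidth(x, power, bandwidths)
  xg <- seq(0, max(x), length.out = 2048L)
  yg <- loclin_fit(x, power, sel$bandwidth, xg)
  keep <- is.finite(yg)  # drop grid points beyond any kernel support
  xg <- xg[keep]; yg <- yg[keep]
  yg <- pmin(pmax(sort(yg), 0), 1)
  list(bandwidth = sel$bandwidth, cv_grid = sel$grid,
       cv_scores = sel$scores, x_grid = xg, curve = yg)
}

# Invert the fitted monotone curve at target power values.
invert_power_curve <- function(fit, betas) {
  rng <- range(fit$curve)
  out_of_range <- betas < rng[1L] | betas > rng[2L]
  if (any(out_of_range))
    stop(sprintf(paste0(
      "target power %.3g outside the fitted curve's attainable range ",
      "[%.3f, %.3f]; extend the scenario grid"),
      betas[which(out_of_range)[1L]], rng[1L], rng[2L]))
  stats::approx(fit$curve, fit$x_grid, xout = betas, ties = "ordered")$y
}

#' Evaluate the calibrated forward power curve
#'
#' @param calibration an `nsc_calibration`.
#' @param alpha one calibrated significance level.
#' @param x corrected scaled statistic values.
#' @return Fitted power at `x`.
#' @export
calibrated_power <- function(calibration, alpha, x) {
  fit <- calibration_fit(calibration, alpha)
  stats::approx(fit$x_grid, fit$curve, xout = x, rule = 2)$y
}

calibration_fit <- function(calibration, alpha) {
  stopifnot(inherits(calibration, "nsc_calibration"))
  j <- match(alpha, calibration$alphas)
  if (is.na(j))
    stop("alpha = ", alpha, " not calibrated; available: ",
         paste(calibration$alphas, collapse = ", "))
  calibration$fits[[j]]
}

#' Look up the calibrated threshold n_sc_star(alpha, beta)
#'
#' Exact matches are read off the calibration table; off-grid `beta`
#' values are interpolated within the `alpha` column. `alpha` must be one
#' of the calibrated levels.
#'
#' @inheritParams calibrated_power
#' @param beta target power, inside the calibrated beta range.
#' @return The threshold value (scalar).
#' @export
nsc_star <- function(calibration, alpha, beta) {
  tab <- calibration$table
  if (inherits(calibration, "nsc_calibration") &&
      !is.null(calibration$fits)) {
    # invert the stored curve directly: exact consistency with the fit
    return(invert_power_curve(calibration_fit(calibration, alpha), beta))
  }
  rows <- tab[tab$alpha == alpha, ]
  if (nrow(rows) == 0L)
    stop("alpha = ", alpha, " not in the calibration table")
  if (beta < min(rows$beta) || beta > max(rows$beta))
    stop("beta = ", beta, " outside the calibrated range [",
         min(rows$beta), ", ", max(rows$beta), "]")
  stats::approx(rows$beta, rows$n_sc_star, xout = beta,
                ties = "ordered")$y
}

#' Save / load a calibration as CSV plus JSON metadata sidecar
#'
#' The CSV holds the `alpha, beta, n_sc_star` table; the sidecar
#' (`<path>.json`) records the settings needed to regenerate it (grid
#' description, n_sim, method, exponent, kernel, seed).
#'
#' @param calibration an `nsc_calibration`.
#' @param path CSV path.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` returns an `nsc_calibration_table` usable with
#'   [nsc_star()].
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "nsc_calibration"))
  utils::write.csv(calibration$table, path, row.names = FALSE,
                   quote = FALSE)
  meta <- calibration[c("alphas", "betas", "exponent", "n_sim", "method",
                        "n_perm", "kernel", "estimator",
                        "bandwidth_rule")]
  meta$seed <- calibration$seed
  meta$n_scenarios <- nrow(calibration$scenarios)
  meta$bandwidths <- vapply(calibration$fits, `[[`, numeric(1),
                            "bandwidth")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("alpha", "beta", "n_sc_star") %in% names(tab)))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list()
  structure(list(table = tab, meta = meta,
                 exponent = if (!is.null(meta$exponent))
                   as.numeric(meta$exponent) else 0.37),
            class = "nsc_calibration_table")
}

#' The packaged default calibration
#'
#' Loads the calibration table shipped with the package, generated by
#' [calibrate_nsc()] over the default grid with the seed recorded in its
#' JSON sidecar.
#'
#' @return An `nsc_calibration_table`.
#' @export
default_calibration <- function() {
  read_calibration(system.file("extdata", "nsc_calibration.csv",
                               package = "haplopower"))
}

#' @export
print.nsc_calibration <- function(x, ...) {
  cat("Calibration of the corrected scaled statistic\n")
  cat(sprintf("  %d scenarios, n_sim = %d per scenario, %s p-values\n",
              nrow(x$scenarios), x$n_sim, x$method))
  cat(sprintf("  exponent %.2f, %s %s regression, %s bandwidth\n",
              x$exponent, x$estimator, x$kernel, x$bandwidth_rule))
  print(utils::head(
    stats::reshape(x$table, idvar = "beta", timevar = "alpha",
                   direction = "wide"), n = 12L))
  invisible(x)
}
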