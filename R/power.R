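#' Study design for a Monte-Carlo power run
#'
#' Bundles the design parameters: arm sizes, significance level, p-value
#' calibration method and replicate counts. `n_controls` can be given
#' directly or via `ratio` = controls per case (controls are then
#' `floor(ratio * n_cases)`).
#'
#' @param n_cases number of cases (>= 1).
#' @param n_controls number of controls (>= 1); alternative to `ratio`.
#' @param ratio control-case ratio r = n_controls / n_cases.
#' @param alpha significance level, strictly in (0, 1).
#' @param method p-value calibration: `"asymptotic"`, `"permutation"` or
#'   `"fisher_mc"`.
#' @param n_sim number of simulated tables.
#' @param n_perm resamples per table for the permutation / Fisher methods.
#' @param seed optional integer RNG seed recorded in results.
#' @return An object of class `study_design`.
#' @examples
#' study_design(n_cases = 300, ratio = 2, method = "permutation",
#'              n_sim = 2000, n_perm = 1000)
#' @export
study_design <- function(n_cases, n_controls = NULL, ratio = NULL,
                         alpha = 0.05,
                         method = c("asymptotic", "permutation",
                                    "fisher_mc"),
                         n_sim = 10000L, n_perm = 1000L, seed = NULL) {
  method <- match.arg(method)
  if (is.null(n_controls)) {
    if (is.null(ratio)) stop("give n_controls or ratio")
    if (ratio <= 0) stop("ratio must be > 0")
    n_controls <- floor(ratio * n_cases)
  } else if (is.null(ratio)) {
    ratio <- n_controls / n_cases
  }
  if (n_cases < 1L || n_controls < 1L) stop("both arms need >= 1 subjects")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)")
  if (n_sim < 1L) stop("n_sim must be >= 1")
  if (method != "asymptotic" && n_perm < 1L)
    stop("n_perm must be >= 1 for resampling methods")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 ratio = ratio, alpha = alpha, method = method,
                 n_sim = as.integer(n_sim), n_perm = as.integer(n_perm),
                 seed = seed),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Study design: %d cases, %d controls (r = %.3g), alpha = %g\n",
    x$n_cases, x$n_controls, x$ratio, x$alpha))
  cat(sprintf("  method = %s, n_sim = %d", x$method, x$n_sim))
  if (x$method != "asymptotic") cat(sprintf(", n_perm = %d", x$n_perm))
  if (!is.null(x$seed)) cat(sprintf(", seed = %d", x$seed))
  cat("\n")
  invisible(x)
}

# Shared Monte-Carlo core: fraction of simulated tables with p < alpha.
power_mc <- function(control_freqs, case_freqs, design) {
  if (!is.null(design$seed)) set.seed(design$seed)
  batch <- simulate_batch(control_freqs, case_freqs, design$n_controls,
                          design$n_cases, design$n_sim)
  p <- batch_pvalues(batch, design$method, design$n_perm,
                     early_alpha = design$alpha)
  pow <- mean(p < design$alpha)
  structure(list(power = pow,
                 mc_se = sqrt(pow * (1 - pow) / design$n_sim),
                 n_sim = design$n_sim, design = design,
                 control_freqs = control_freqs, case_freqs = case_freqs,
                 seed = design$seed),
            class = "power_estimate")
}

#' A-priori power of a 2xk case-control study
#'
#' Estimates power as the fraction of `n_sim` simulated tables (controls
#' from the null spectrum, cases from the effect-shifted frequencies) whose
#' p-value falls below `alpha`. The Monte-Carlo standard error is the
#' binomial `sqrt(power * (1 - power) / n_sim)`.
#'
#' @param spectrum a [category_spectrum()] of control frequencies.
#' @param effect an [effect_spec()]; use [null_effect()] for a type-I-error
#'   run.
#' @param design a [study_design()].
#' @return A `power_estimate`: `power`, `mc_se`, `n_sim`, `design`,
#'   `effect`, `seed`.
#' @examples
#' sp <- euro11_spectrum()
#' d <- study_design(n_cases = 200, ratio = 1, n_sim = 500, seed = 1)
#' estimate_power(sp, effect_spec("J", deviation = 1), d)
#' @export
estimate_power <- function(spectrum, effect, design) {
  stopifnot(inherits(spectrum, "category_spectrum"),
            inherits(effect, "effect_spec"),
            inherits(design, "study_design"))
  case_freqs <- build_case_frequencies(spectrum, effect)
  out <- power_mc(spectrum$freqs, as.numeric(case_freqs), design)
  out$effect <- effect
  out$labels <- spectrum$labels
  out
}

#' A-posteriori power from an observed table
#'
#' Prospective power at the observed effect: the observed row proportions
#' are taken as the true control and case frequency vectors and the
#' observed row totals as the arm sizes, then the Monte-Carlo machinery of
#' [estimate_power()] is applied unchanged. (This is *not* the
#' "observed power" transformation of the achieved p-value criticized in
#' the post-hoc-power literature; it answers "what power would a new study
#' of this size and these frequencies have".)
#'
#' @param observed a [count_table()] (categories with zero count in both
#'   rows are dropped first).
#' @param alpha significance level.
#' @param method,n_sim,n_perm,seed as in [study_design()].
#' @return A `power_estimate`.
#' @examples
#' tab <- count_table(rbind(c(60, 40), c(40, 60)))
#' posthoc_power(tab, n_sim = 500, seed = 1)
#' @export
posthoc_power <- function(observed, alpha = 0.05,
                          method = c("asymptotic", "permutation",
                                     "fisher_mc"),
                          n_sim = 10000L, n_perm = 1000L, seed = NULL) {
  method <- match.arg(method)
  m <- as_table_matrix(observed)
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2L)
    stop("observed table has fewer than 2 non-empty categories")
  n_co <- sum(m[1L, ]); n_ca <- sum(m[2L, ])
  design <- study_design(n_cases = n_ca, n_controls = n_co, alpha = alpha,
                         method = method, n_sim = n_sim, n_perm = n_perm,
                         seed = seed)
  out <- power_mc(m[1L, ] / n_co, m[2L, ] / n_ca, design)
  out$labels <- colnames(m)
  out$observed <- m
  out
}

#' @export
print.power_estimate <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "Monte-Carlo power estimate: %.4f (MC SE %.4f)\n", x$power, x$mc_se))
  cat(sprintf("  %d cases / %d controls, alpha = %g, method = %s\n",
              d$n_cases, d$n_controls, d$alpha, d$method))
  cat(sprintf("  n_sim = %d", x$n_sim))
  if (d$method != "asymptotic") cat(sprintf(", n_perm = %d", d$n_perm))
  if (!is.null(x$seed)) cat(sprintf(", seed = %d", x$seed))
  cat("\n")
  invisible(x)
}
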