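#' Specify the effect: how the risky category deviates in cases
#'
#' The alternative hypothesis is an increase of one "risky" category's
#' frequency in cases relative to controls, with the difference
#' redistributed proportionally over the remaining categories. The effect
#' can be given in exactly one of three equivalent parameterizations:
#'
#' * `deviation`: relative increase delta, so the case frequency is
#'   `p1 = p0 * (1 + delta)` (delta = 1 means "100% higher in cases");
#' * `case_freq`: the target case frequency `p1` directly;
#' * `odds_ratio`: the case/control odds ratio for the risky category.
#'
#' All three are mutually convertible given the control frequency `p0`
#' (see [effect_as_or()], [or_to_p1()]) and must imply `p0 <= p1 < 1`.
#'
#' @param risky category selector: an index or a label (resolved against a
#'   spectrum when the effect is applied).
#' @param deviation relative deviation delta >= 0.
#' @param case_freq target case frequency p1.
#' @param odds_ratio odds ratio >= 1.
#' @return An object of class `effect_spec`.
#' @examples
#' effect_spec("J", deviation = 1)       # J twice as frequent in cases
#' effect_spec(1, odds_ratio = 1.5)
#' @export
effect_spec <- function(risky, deviation = NULL, case_freq = NULL,
                        odds_ratio = NULL) {
  given <- !c(is.null(deviation), is.null(case_freq), is.null(odds_ratio))
  if (sum(given) != 1L)
    stop("give exactly one of deviation, case_freq, odds_ratio")
  if (!is.null(deviation) && (!is.finite(deviation) || deviation < 0))
    stop("deviation must be a finite number >= 0")
  if (!is.null(case_freq) && (!is.finite(case_freq) || case_freq <= 0 ||
                              case_freq >= 1))
    stop("case_freq must lie strictly in (0, 1)")
  if (!is.null(odds_ratio) && (!is.finite(odds_ratio) || odds_ratio < 1))
    stop("odds_ratio must be finite and >= 1")
  structure(list(risky = risky, deviation = deviation,
                 case_freq = case_freq, odds_ratio = odds_ratio),
            class = "effect_spec")
}

#' Null effect helper (delta = 0)
#' @param risky category selector; irrelevant under the null but kept for
#'   provenance.
#' @return An `effect_spec` with zero deviation.
#' @export
null_effect <- function(risky = 1L) effect_spec(risky, deviation = 0)

# Resolve the risky selector to a column index of a spectrum.
resolve_risky <- function(spectrum, risky) {
  if (is.character(risky)) {
    i <- match(risky, spectrum$labels)
    if (is.na(i)) stop("unknown category label '", risky, "'")
    return(i)
  }
  i <- as.integer(risky)
  if (is.na(i) || i < 1L || i > spectrum$k)
    stop("risky index out of range 1..", spectrum$k)
  i
}

# p0 + effect -> p1, with the feasibility check p1 < 1.
resolve_p1 <- function(p0, effect) {
  stopifnot(inherits(effect, "effect_spec"))
  p1 <- if (!is.null(effect$deviation)) {
    p0 * (1 + effect$deviation)
  } else if (!is.null(effect$case_freq)) {
    effect$case_freq
  } else {
    or_to_p1(effect$odds_ratio, p0)
  }
  if (p1 >= 1)
    stop(sprintf(paste0(
      "infeasible effect: implied case frequency p1 = %.4g >= 1 ",
      "(maximum admissible deviation for p0 = %.4g is delta = %.4g)"),
      p1, p0, 1 / p0 - 1))
  if (p1 < p0)
    stop("implied case frequency p1 = ", signif(p1, 4),
         " is below the control frequency p0 = ", signif(p0, 4),
         "; only increases of the risky category are modelled")
  p1
}

#' Build the case-arm frequency vector from a spectrum and an effect
#'
#' The risky category's frequency becomes `p1 = p0 * (1 + delta)`; every
#' other category `q_j` is scaled by `(1 - p1) / (1 - p0)`, i.e. the
#' difference is distributed proportionally over the non-risky categories.
#' The output sums to one.
#'
#' @param spectrum a [category_spectrum()] (control frequencies).
#' @param effect an [effect_spec()].
#' @return Numeric vector of case frequencies, named by category label.
#' @examples
#' sp <- category_spectrum(c(a = 0.4, b = 0.3, c = 0.3))
#' build_case_frequencies(sp, effect_spec("a", deviation = 0.5))
#' @export
build_case_frequencies <- function(spectrum, effect) {
  stopifnot(inherits(spectrum, "category_spectrum"))
  i <- resolve_risky(spectrum, effect$risky)
  p0 <- spectrum$freqs[i]
  p1 <- resolve_p1(p0, effect)
  out <- spectrum$freqs * (1 - p1) / (1 - p0)
  out[i] <- p1
  stats::setNames(out, spectrum$labels)
}

#' Odds ratio for a case/control frequency pair
#'
#' `effect_as_or()` maps control frequency `p0` and case frequency `p1` to
#' the odds ratio `(p1/(1-p1)) / (p0/(1-p0))`; `or_to_p1()` is the inverse
#' conversion back to `p1`.
#'
#' @param p0 control frequency in (0, 1).
#' @param p1 case frequency in (0, 1).
#' @return The odds ratio (or, for `or_to_p1`, the case frequency).
#' @examples
#' effect_as_or(0.11, 0.22)
#' or_to_p1(effect_as_or(0.11, 0.22), 0.11)
#' @export
effect_as_or <- function(p0, p1) {
  check_freq(p0, "p0"); check_freq(p1, "p1")
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

#' @rdname effect_as_or
#' @param or odds ratio > 0.
#' @export
or_to_p1 <- function(or, p0) {
  check_freq(p0, "p0")
  if (any(!is.finite(or) | or <= 0)) stop("odds ratio must be > 0")
  o <- or * p0 / (1 - p0)
  o / (1 + o)
}

check_freq <- function(p, what) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop(what, " must lie strictly in (0, 1)")
  invisible(p)
}
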