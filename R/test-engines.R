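#' Pearson chi-square statistic of a 2xk table
#'
#' Computes the uncorrected Pearson statistic, sum over cells of
#' `(O - E)^2 / E`, with expected counts from the product-of-margins rule.
#' No continuity correction is applied (the power machinery requires the
#' raw statistic, also for 2x2 tables). Columns whose total is zero carry
#' no information and are dropped with a warning; a zero *row* sum is an
#' error.
#'
#' @param table a [count_table()] or a 2xk matrix of counts.
#' @return The statistic (non-negative scalar).
#' @examples
#' chisq_stat(rbind(c(10, 0), c(0, 10)))  # 20
#' @export
chisq_stat <- function(table) {
  m <- drop_empty_columns(as_table_matrix(table))
  e <- expected_counts(m)
  sum((m - e)^2 / e)
}

as_table_matrix <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != 2L) stop("expected a 2-row table")
  if (any(rowSums(m) == 0))
    stop("degenerate table: a zero row sum")
  m
}

drop_empty_columns <- function(m) {
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning(sum(empty), " all-zero column(s) dropped before computation")
    m <- m[, !empty, drop = FALSE]
  }
  m
}

expected_counts <- function(m) {
  outer(rowSums(m), colSums(m)) / sum(m)
}

#' Cochran's adequacy rule for the asymptotic chi-square
#'
#' TRUE iff no expected cell count is below one and at most 20% of the
#' expected cells are below five; when it fails, the asymptotic p-value is
#' known to inflate the false-positive rate and the permutation calibration
#' should be preferred.
#'
#' @inheritParams chisq_stat
#' @return Logical flag.
#' @examples
#' cochran_rule_ok(rbind(c(50, 50), c(50, 50)))  # TRUE
#' @export
cochran_rule_ok <- function(table) {
  m <- suppressWarnings(drop_empty_columns(as_table_matrix(table)))
  e <- expected_counts(m)
  min(e) >= 1 && sum(e < 5) <= 0.2 * length(e)
}

test_result <- function(statistic, p_value, method, n_perm, cochran_ok,
                        df = NA_real_) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n_perm = n_perm, cochran_ok = cochran_ok, df = df),
            class = "table_test")
}

#' @export
print.table_test <- function(x, ...) {
  cat("2xk homogeneity test (", x$method, " calibration)\n", sep = "")
  cat(sprintf("  chi-square = %.4f", x$statistic))
  if (!is.na(x$df)) cat(", df =", x$df)
  cat(sprintf(", p = %.4g\n", x$p_value))
  if (x$n_perm > 0) cat("  resamples:", x$n_perm, "\n")
  if (!x$cochran_ok)
    cat("  note: Cochran's rule fails; asymptotic p-values unreliable\n")
  invisible(x)
}

#' Homogeneity p-values for a 2xk table
#'
#' Three calibrations of the Pearson statistic's null distribution:
#'
#' * `pvalue_asymptotic()`: upper chi-square tail with `k' - 1` degrees of
#'   freedom, `k'` the number of non-empty columns;
#' * `pvalue_permutation()`: `B` tables resampled with both margins fixed
#'   (sequential conditional hypergeometric columns, equivalent to
#'   Patefield's algorithm); `p = (1 + #\{resampled statistic >= observed\})
#'   / (B + 1)`, which is strictly positive and valid;
#' * `pvalue_fisher_mc()`: Monte-Carlo Fisher exact test — the same
#'   margin-fixed resampling, but a table counts as extreme when its
#'   conditional (multivariate hypergeometric) probability does not exceed
#'   the observed table's.
#'
#' @inheritParams chisq_stat
#' @return A `table_test` object: `statistic`, `p_value`, `method`,
#'   `n_perm`, `cochran_ok`, `df`.
#' @examples
#' t <- count_table(rbind(c(30, 70), c(50, 50)))
#' pvalue_asymptotic(t)
#' set.seed(1)
#' pvalue_permutation(t, B = 2000)
#' @export
pvalue_asymptotic <- function(table) {
  m <- drop_empty_columns(as_table_matrix(table))
  stat <- sum((m - expected_counts(m))^2 / expected_counts(m))
  df <- ncol(m) - 1
  p <- if (df < 1) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  test_result(stat, p, "asymptotic", 0L, cochran_rule_ok(m), df)
}

#' @rdname pvalue_asymptotic
#' @param B number of margin-fixed resamples.
#' @export
pvalue_permutation <- function(table, B = 10000L) {
  m <- drop_empty_columns(as_table_matrix(table))
  p <- perm_pvalues_cpp(matrix(as.integer(m[1L, ])),
                        matrix(as.integer(m[2L, ])), as.integer(B))[1L]
  stat <- sum((m - expected_counts(m))^2 / expected_counts(m))
  test_result(stat, p, "permutation", as.integer(B), cochran_rule_ok(m),
              ncol(m) - 1)
}

#' @rdname pvalue_asymptotic
#' @export
pvalue_fisher_mc <- function(table, B = 10000L) {
  m <- drop_empty_columns(as_table_matrix(table))
  p <- fisher_pvalues_cpp(matrix(as.integer(m[1L, ])),
                          matrix(as.integer(m[2L, ])), as.integer(B))[1L]
  stat <- sum((m - expected_counts(m))^2 / expected_counts(m))
  test_result(stat, p, "fisher_mc", as.integer(B), cochran_rule_ok(m),
              ncol(m) - 1)
}

#' Resample a 2xk table with both margins fixed
#'
#' Draws `B` tables uniformly from the hypergeometric null given the
#' observed row and column totals; exposed mainly for validation (the MC
#' p-value engines use the same sampler internally).
#'
#' @inheritParams chisq_stat
#' @param B number of tables to draw.
#' @return List of `B` 2xk integer matrices.
#' @export
sample_margin_fixed <- function(table, B) {
  m <- as_table_matrix(table)
  storage.mode(m) <- "integer"
  sample_margin_fixed_cpp(m, as.integer(B))
}

# Vectorized p-values for a simulated batch. X0, X1: k x n count matrices.
# method "asymptotic" runs fully vectorized in R; the resampling methods
# call the compiled engines. early_alpha > 0 lets those engines stop a
# table's resampling once its p-value is guaranteed >= early_alpha (the
# rejection indicators at any level <= early_alpha are unchanged; only
# power runs use this).
batch_pvalues <- function(batch, method, B = 1000L, early_alpha = 0) {
  X0 <- batch$controls; X1 <- batch$cases
  if (method == "asymptotic") {
    M <- X0 + X1
    n0 <- batch$n_controls; n1 <- batch$n_cases
    N <- n0 + n1
    E0 <- M * (n0 / N)
    E1 <- M * (n1 / N)
    T0 <- (X0 - E0)^2
    T1 <- (X1 - E1)^2
    nz <- M > 0
    T0[nz] <- T0[nz] / E0[nz]; T0[!nz] <- 0
    T1[nz] <- T1[nz] / E1[nz]; T1[!nz] <- 0
    stat <- colSums(T0 + T1)
    df <- colSums(nz) - 1
    p <- rep(1, length(stat))
    ok <- df >= 1
    p[ok] <- stats::pchisq(stat[ok], df[ok], lower.tail = FALSE)
    p
  } else if (method == "permutation") {
    perm_pvalues_cpp(X0, X1, as.integer(B), early_alpha)
  } else if (method == "fisher_mc") {
    fisher_pvalues_cpp(X0, X1, as.integer(B), early_alpha)
  } else stop("unknown method '", method, "'")
}
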