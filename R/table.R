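#' 2xk case-control count table
#'
#' Wraps a 2-by-k matrix of non-negative integer counts, row 1 = controls,
#' row 2 = cases, columns = marker categories.
#'
#' @param counts 2xk matrix (or something coercible) of non-negative
#'   integers.
#' @param labels optional category labels (defaults to column names).
#' @return An object of class `count_table`: the integer matrix with
#'   rownames `controls`/`cases`.
#' @examples
#' count_table(rbind(c(60, 40), c(40, 60)), labels = c("A", "B"))
#' @export
count_table <- function(counts, labels = NULL) {
  m <- as.matrix(counts)
  if (nrow(m) != 2L) stop("a count table has exactly 2 rows, got ", nrow(m))
  if (ncol(m) < 1L) stop("a count table needs at least 1 column")
  if (any(!is.finite(m) | m < 0 | m != round(m)))
    stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  if (is.null(labels)) {
    labels <- colnames(m)
    if (is.null(labels)) labels <- paste0("cat", seq_len(ncol(m)))
  }
  dimnames(m) <- list(c("controls", "cases"), as.character(labels))
  structure(m, class = c("count_table", "matrix", "array"))
}

#' Read / write a 2xk count table as CSV
#'
#' Format: a header row of category labels plus a leading `group` column,
#' then a `controls` row and a `cases` row of integer counts.
#'
#' @param path CSV path.
#' @return `read_count_table` returns a [count_table()];
#'   `write_count_table` returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1L] != "group")
    stop("count-table CSV must start with a 'group' column")
  rows <- match(c("controls", "cases"), df$group)
  if (any(is.na(rows)))
    stop("count-table CSV needs 'controls' and 'cases' rows")
  m <- as.matrix(df[rows, -1L, drop = FALSE])
  count_table(m, labels = names(df)[-1L])
}

#' @rdname read_count_table
#' @param table a [count_table()].
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(group = rownames(table), unclass(table)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate one 2xk table by independent multinomial sampling
#'
#' The control row is Multinomial(`n_controls`, `control_freqs`) and the
#' case row, independently, Multinomial(`n_cases`, `case_freqs`); this is
#' the generative model for both the null (equal frequency vectors) and the
#' alternative (case frequencies built by [build_case_frequencies()]).
#'
#' @param control_freqs,case_freqs frequency vectors of equal length k,
#'   each summing to 1.
#' @param n_controls,n_cases arm sizes (non-negative integers).
#' @param labels optional category labels.
#' @return A [count_table()].
#' @examples
#' set.seed(1)
#' simulate_table(c(0.5, 0.5), c(0.7, 0.3), 100, 100)
#' @export
simulate_table <- function(control_freqs, case_freqs, n_controls, n_cases,
                           labels = NULL) {
  b <- simulate_batch(control_freqs, case_freqs, n_controls, n_cases,
                      n_sim = 1L)
  count_table(rbind(b$controls[, 1L], b$cases[, 1L]),
              labels = if (is.null(labels)) names(control_freqs) else labels)
}

#' Simulate a batch of 2xk tables
#'
#' Draws `n_sim` independent tables; internally the batch is stored as two
#' k-by-n_sim count matrices (one per arm) so downstream statistics can be
#' computed by matrix operations.
#'
#' @inheritParams simulate_table
#' @param n_sim number of tables.
#' @return An object of class `table_batch`: a list with `controls` and
#'   `cases` (k x n_sim integer matrices), `n_controls`, `n_cases`.
#' @export
simulate_batch <- function(control_freqs, case_freqs, n_controls, n_cases,
                           n_sim) {
  control_freqs <- as.numeric(control_freqs)
  case_freqs <- as.numeric(case_freqs)
  if (length(control_freqs) != length(case_freqs))
    stop("control and case frequency vectors differ in length (",
         length(control_freqs), " vs ", length(case_freqs), ")")
  if (abs(sum(control_freqs) - 1) > 1e-8 || abs(sum(case_freqs) - 1) > 1e-8)
    stop("frequency vectors must each sum to 1")
  if (n_sim < 1L) stop("n_sim must be >= 1")
  if (n_controls < 0L || n_cases < 0L) stop("arm sizes must be >= 0")
  k <- length(control_freqs)
  draw <- function(n, p) {
    if (n == 0L) matrix(0L, k, n_sim) else stats::rmultinom(n_sim, n, p)
  }
  structure(list(controls = draw(n_controls, control_freqs),
                 cases = draw(n_cases, case_freqs),
                 n_controls = as.integer(n_controls),
                 n_cases = as.integer(n_cases)),
            class = "table_batch")
}

# i-th table of a batch as a count_table
batch_table <- function(batch, i, labels = NULL) {
  count_table(rbind(batch$controls[, i], batch$cases[, i]), labels = labels)
}

#' @export
print.count_table <- function(x, ...) {
  cat("2x", ncol(x), " case-control count table\n", sep = "")
  print(unclass(x))
  invisible(x)
}
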