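#' Category frequency spectrum for the control population
#'
#' A `category_spectrum` holds the labelled frequency vector of the k marker
#' categories (haplogroups, haplotypes, mtSNP classes, ...) in the control
#' (null) population. Frequencies must be strictly positive and are
#' renormalized to sum exactly to one; a warning is emitted when the raw sum
#' deviates from one by more than `1e-6`, so that typos in published
#' frequency tables stay visible.
#'
#' @param freqs numeric vector of category frequencies, each in (0, 1).
#' @param labels character vector of category names; defaults to
#'   `names(freqs)` or `"cat1"..."catk"`.
#' @return An object of class `category_spectrum`: a list with elements
#'   `labels`, `freqs` (renormalized), `raw_sum` and `k`.
#' @examples
#' sp <- category_spectrum(c(H = 0.4, J = 0.3, U = 0.3))
#' sp$freqs
#' @export
category_spectrum <- function(freqs, labels = NULL) {
  if (is.null(labels)) {
    labels <- names(freqs)
    if (is.null(labels)) labels <- paste0("cat", seq_along(freqs))
  }
  freqs <- as.numeric(freqs)
  if (length(freqs) < 2L)
    stop("a spectrum needs at least 2 categories, got ", length(freqs))
  if (length(labels) != length(freqs))
    stop("labels and freqs differ in length (", length(labels), " vs ",
         length(freqs), ")")
  bad <- which(!is.finite(freqs) | freqs <= 0)
  if (length(bad))
    stop("non-positive or non-numeric frequency for category '",
         labels[bad[1L]], "' (row ", bad[1L], ")")
  raw_sum <- sum(freqs)
  if (abs(raw_sum - 1) > 1e-6)
    warning(sprintf(
      "frequencies sum to %.6g, not 1; renormalizing", raw_sum))
  structure(
    list(labels = as.character(labels), freqs = freqs / raw_sum,
         raw_sum = raw_sum, k = length(freqs)),
    class = "category_spectrum")
}

#' Read a frequency spectrum from CSV
#'
#' Expects a two-column CSV with header `label,freq` ('.' decimal separator),
#' one row per category. Frequencies are renormalized on load (see
#' [category_spectrum()]).
#'
#' @param path path to the CSV file.
#' @return A [category_spectrum()].
#' @examples
#' sp <- read_spectrum(system.file("extdata", "euro11.csv",
#'                                 package = "haplopower"))
#' @export
read_spectrum <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed spectrum CSV '", path, "': ",
                             conditionMessage(e)))
  if (!all(c("label", "freq") %in% names(df)))
    stop("spectrum CSV must have header 'label,freq', got: ",
         paste(names(df), collapse = ","))
  if (nrow(df) < 2L)
    stop("spectrum CSV needs at least 2 rows, got ", nrow(df))
  f <- suppressWarnings(as.numeric(df$freq))
  bad <- which(is.na(f))
  if (length(bad))
    stop("non-numeric frequency in row ", bad[1L], " (label '",
         df$label[bad[1L]], "')")
  category_spectrum(f, labels = df$label)
}

#' Write a spectrum to CSV (header `label,freq`)
#' @param spectrum a [category_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "category_spectrum"))
  utils::write.csv(
    data.frame(label = spectrum$labels, freq = spectrum$freqs),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The 11-haplogroup European example spectrum
#'
#' Loads the packaged example spectrum of 11 European mtDNA haplogroup
#' frequencies (H, I, J, K, M, T, U, V, W, X plus a residual class). The
#' file ships the published values verbatim, which sum to 110%, so loading
#' renormalizes them and warns; pass `quiet = TRUE` to suppress the warning.
#'
#' @param quiet suppress the renormalization warning.
#' @return A [category_spectrum()] with k = 11.
#' @export
euro11_spectrum <- function(quiet = TRUE) {
  path <- system.file("extdata", "euro11.csv", package = "haplopower")
  if (quiet) suppressWarnings(read_spectrum(path)) else read_spectrum(path)
}

#' @export
print.category_spectrum <- function(x, ...) {
  cat("Category spectrum (k =", x$k, "categories)\n")
  print(stats::setNames(round(x$freqs, 4), x$labels))
  if (abs(x$raw_sum - 1) > 1e-6)
    cat(sprintf("(raw frequencies summed to %.4g; renormalized)\n",
                x$raw_sum))
  invisible(x)
}
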