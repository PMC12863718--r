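#' Labeled contingency table
#'
#' A thin matrix wrapper holding non-negative integer counts with row and
#' column labels, the common currency between the cross-tabulation,
#' association-testing and chromosome-accounting functions.
#'
#' @param counts numeric matrix (or object coercible to one) of non-negative
#'   counts.
#' @param row_labels,col_labels character vectors; default to the matrix
#'   dimnames.
#' @return matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0))
    tc4_stop("triC4_bad_counts", "counts must be non-negative and non-missing")
  if (is.null(row_labels)) row_labels <- as.character(seq_len(nrow(counts)))
  if (is.null(col_labels)) col_labels <- as.character(seq_len(ncol(counts)))
  if (length(row_labels) != nrow(counts) || length(col_labels) != ncol(counts))
    tc4_stop("triC4_bad_counts", "label length does not match table dimensions")
  dimnames(counts) <- list(row_labels, col_labels)
  class(counts) <- c("contingency_table", class(counts))
  counts
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table (", nrow(x), "x", ncol(x), ", N = ", sum(x), ")\n", sep = "")
  m <- rbind(cbind(unclass(x), All = rowSums(x)), All = c(colSums(x), sum(x)))
  print(m, ...)
  invisible(x)
}

#' Pearson chi-squared test of independence
#'
#' Computes the Pearson statistic \eqn{\sum (O-E)^2/E} on an R x C table with
#' expected counts from the row/column margins and no continuity correction.
#' All-zero rows and columns are dropped before testing and the degrees of
#' freedom are computed on the retained dimensions, \eqn{(r-1)(c-1)}.
#' Expected counts below 5 are reported as a warning flag (not an error),
#' matching common practice for sparse genotype tables.
#'
#' @param table a [contingency_table] or plain count matrix.
#' @return list of class `chisq_result` with `statistic`, `df`, `p_value`,
#'   and `warnings` (character vector, possibly empty).
#' @export
pearson_chisq <- function(table) {
  m <- unclass(as.matrix(table))
  if (any(m < 0) || sum(m) <= 0)
    tc4_stop("triC4_bad_counts", "table must be non-negative with positive total")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    tc4_stop("triC4_degenerate_table",
             "fewer than 2 non-degenerate rows or columns after dropping zeros")
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  warn <- character()
  if (any(E < 5)) warn <- "expected counts below 5 in some cells"
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 warnings = warn),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: statistic = %.4g, df = %d, p = %s\n",
              x$statistic, x$df, format(signif(x$p_value, 3), scientific = TRUE)))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Fractions of a contingency table
#'
#' Exact integer numerator/denominator (and the float fraction) for a row,
#' column or cell of a table relative to its grand total -- the form in which
#' descriptive results such as "56.9% (107/188) of the samples were C4A null"
#' are reported.
#'
#' @param table a [contingency_table].
#' @param row,col row/column label (character) or NULL for all.
#' @return list with `numerator`, `denominator`, `fraction`.
#' @export
summarize_fractions <- function(table, row = NULL, col = NULL) {
  m <- as.matrix(table)
  pick <- function(labels, q, axis) {
    if (is.null(q)) return(seq_along(labels))
    i <- match(as.character(q), labels)
    if (any(is.na(i)))
      tc4_stop("triC4_label", sprintf("unknown %s label: %s", axis,
                                      paste(q[is.na(i)], collapse = ", ")))
    i
  }
  ri <- pick(rownames(m), row, "row")
  ci <- pick(colnames(m), col, "column")
  num <- sum(m[ri, ci])
  list(numerator = num, denominator = sum(m), fraction = num / sum(m))
}

#' Cross-tabulate C4 copy-number calls against tri-SNP 101 dosage
#'
#' @param calls data.frame with columns `gcn_a`, `gcn_b` (as produced by
#'   [call_c4()]) or a vector of copy numbers via `gcn`.
#' @param dosage integer vector in 0..2, the per-sample count of tri-SNP 101
#'   alleles.
#' @param paralog `"A"` or `"B"`: which paralog's copy number forms the rows.
#' @param gcn optional explicit copy-number vector overriding `calls`.
#' @return [contingency_table]: rows = observed copy numbers ascending,
#'   columns = dosage 0, 1, 2.
#' @export
build_gcn_table <- function(calls = NULL, dosage, paralog = c("A", "B"), gcn = NULL) {
  paralog <- match.arg(paralog)
  if (is.null(gcn))
    gcn <- if (paralog == "A") calls$gcn_a else calls$gcn_b
  if (length(gcn) == 0L) tc4_stop("triC4_no_data", "no copy-number calls supplied")
  if (length(gcn) != length(dosage))
    tc4_stop("triC4_bad_counts", "calls and dosage lengths differ")
  if (!all(dosage %in% 0:2)) tc4_stop("triC4_bad_counts", "dosage must be 0, 1 or 2")
  rows <- sort(unique(gcn))
  m <- table(factor(gcn, levels = rows), factor(dosage, levels = 0:2))
  contingency_table(matrix(as.integer(m), nrow = length(rows),
                           dimnames = list(as.character(rows), as.character(0:2))))
}
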