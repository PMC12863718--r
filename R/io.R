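#' Write a contingency table as TSV with margins
#'
#' Appends row and column totals ("All") before writing; the layout used for
#' the HLA x tri-SNP distribution table.
#'
#' @param table a [contingency_table()].
#' @param path output path.
#' @export
write_crosstab_tsv <- function(table, path) {
  m <- as.matrix(table)
  out <- rbind(cbind(m, All = rowSums(m)), All = c(colSums(m), sum(m)))
  df <- data.frame(label = rownames(out), out, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a chi-squared result as JSON
#'
#' @param result a `chisq_result` from [pearson_chisq()].
#' @param path output path.
#' @export
write_chisq_json <- function(result, path) {
  writeLines(jsonlite::toJSON(list(statistic = result$statistic, df = result$df,
                                   p_value = result$p_value,
                                   warnings = result$warnings),
                              auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
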