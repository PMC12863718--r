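#' Expression set container
#'
#' Gene x sample integer counts with the sample covariates the dosage-trend
#' model needs: sequencing batch, age category (younger/older than 1 year),
#' sex, and the sample-to-individual map; tri-SNP 101 dosage is attached per
#' individual.
#'
#' @param counts non-negative integer matrix, genes x samples, with dimnames.
#' @param samples data.frame with columns `sample_id`, `individual_id`,
#'   `batch`, `age_cat` (`"lt1y"`/`"ge1y"`), `sex`; one row per count column
#'   in order.
#' @param dosage named numeric vector of tri-SNP 101 dosages, one per
#'   individual.
#' @return list of class `expression_set`.
#' @export
expression_set <- function(counts, samples, dosage) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) tc4_stop("triC4_bad_counts", "counts must be non-negative")
  if (ncol(counts) != nrow(samples))
    tc4_stop("triC4_bad_counts", "one samples row per count column is required")
  if (!all(samples$individual_id %in% names(dosage)))
    tc4_stop("triC4_no_data", "every sample must map to an individual with a dosage")
  structure(list(counts = counts, samples = samples, dosage = dosage),
            class = "expression_set")
}

#' Counts per million
#'
#' cpm = count / library size x 1e6, with the library size of a sample being
#' its column sum (or supplied explicitly). Columns of the result sum to 1e6.
#'
#' @param counts matrix of counts or an [expression_set()].
#' @param lib_sizes optional numeric vector of library sizes per sample.
#' @return numeric matrix of CPM values.
#' @export
compute_cpm <- function(counts, lib_sizes = NULL) {
  if (inherits(counts, "expression_set")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0))
    tc4_stop("triC4_library_size", "zero library size")
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Per-individual aggregation of CPM values
#'
#' Median CPM over an individual's samples, per gene; individuals with a
#' single sample pass through unchanged.
#'
#' @param cpm genes x samples matrix.
#' @param individual_id character vector mapping each sample column to an
#'   individual.
#' @return genes x individuals matrix (individuals in first-appearance
#'   order).
#' @export
aggregate_per_individual <- function(cpm, individual_id) {
  if (ncol(cpm) != length(individual_id))
    tc4_stop("triC4_bad_counts", "one individual id per sample column is required")
  inds <- unique(individual_id)
  out <- vapply(inds, function(id) {
    cols <- which(individual_id == id)
    if (length(cols) == 1L) cpm[, cols] else apply(cpm[, cols, drop = FALSE], 1, median)
  }, numeric(nrow(cpm)))
  out <- matrix(out, nrow = nrow(cpm), dimnames = list(rownames(cpm), inds))
  out
}

#' Per-gene tri-SNP dosage trend on aggregated expression
#'
#' For every gene, ordinary least squares of log2(median CPM + 0.5) on
#' sequencing batch, age category, sex and the numeric tri-SNP 101 dosage,
#' at the individual level (per-individual covariates are taken from the
#' individual's first sample). Two-sided t-test on the dosage coefficient,
#' Benjamini-Hochberg adjustment across genes. This is a documented
#' simplification of moderated per-sample modeling with an individual
#' blocking factor: aggregation removes the within-individual correlation
#' instead.
#'
#' @param es an [expression_set()].
#' @param offset pseudo-count added before the log2 transform (default 0.5,
#'   avoiding -Inf at zero counts while preserving ordering).
#' @return data.frame of class `trend_result`: `gene`, `coefficient`
#'   (log2-CPM per 101 allele), `t`, `p_value`, `bh_adjusted_p`.
#' @export
dosage_trend <- function(es, offset = 0.5) {
  cpm <- compute_cpm(es)
  agg <- aggregate_per_individual(cpm, es$samples$individual_id)
  inds <- colnames(agg)
  first <- es$samples[!duplicated(es$samples$individual_id), ]
  first <- first[match(inds, first$individual_id), ]
  dos <- es$dosage[inds]
  if (length(unique(dos)) < 2L)
    tc4_stop("triC4_design", "at least two dosage levels are required")
  df <- data.frame(batch = factor(first$batch), age_cat = factor(first$age_cat),
                   sex = factor(first$sex), dosage = as.numeric(dos))
  keep <- vapply(c("batch", "age_cat", "sex"), function(v) nlevels(df[[v]]) > 1,
                 logical(1))
  fml <- as.formula(paste("~", paste(c(names(keep)[keep], "dosage"), collapse = " + ")))
  X <- model.matrix(fml, df)
  if (qr(X)$rank < ncol(X))
    tc4_stop("triC4_design", "collinear design matrix")
  Y <- t(log2(agg + offset))               # individuals x genes
  qx <- qr(X)
  B <- qr.coef(qx, Y)                      # coefficients x genes
  res <- Y - X %*% B
  dfree <- nrow(X) - ncol(X)
  if (dfree < 1L) tc4_stop("triC4_design", "not enough individuals for the design")
  s2 <- colSums(res^2) / dfree
  XtXinv <- chol2inv(qr.R(qx))
  j <- match("dosage", colnames(X))
  se <- sqrt(s2 * XtXinv[j, j])
  beta <- B[j, ]
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), dfree)
  out <- data.frame(gene = rownames(agg), coefficient = unname(beta),
                    t = unname(tstat), p_value = unname(p),
                    bh_adjusted_p = p.adjust(unname(p), method = "BH"),
                    stringsAsFactors = FALSE)
  class(out) <- c("trend_result", class(out))
  attr(out, "n_individuals") <- nrow(X)
  attr(out, "df_residual") <- dfree
  out
}

#' Per-individual C4 expression summary
#'
#' Long-format summary of median CPM per individual for designated genes
#' (by default the C4A-like and C4B-like genes of the generator), alongside
#' the individual's tri-SNP 101 dosage -- the table behind a
#' dosage-stratified box plot.
#'
#' @param es an [expression_set()].
#' @param genes character vector of gene ids.
#' @return data.frame: `individual_id`, `dosage`, one column per gene.
#' @export
c4_expression_summary <- function(es, genes = c("C4A_like", "C4B_like")) {
  genes <- intersect(genes, rownames(es$counts))
  if (!length(genes)) tc4_stop("triC4_label", "none of the requested genes present")
  agg <- aggregate_per_individual(compute_cpm(es), es$samples$individual_id)
  out <- data.frame(individual_id = colnames(agg),
                    dosage = as.numeric(es$dosage[colnames(agg)]))
  for (g in genes) out[[g]] <- agg[g, ]
  out
}
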