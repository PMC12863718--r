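#' Call tri-SNP genotypes for every sample in a phased VCF
#'
#' Reads a VCF (plain or bgzipped; parsed with `VariantAnnotation`), locates
#' the three tri-SNP sites by ID (falling back to chrom:pos from the
#' definition), and calls each sample's tri-SNP genotype. Phase is taken from
#' the GT separator per call: "|" phased, "/" unphased (unphased calls are
#' accepted only when heterozygous at no more than one site).
#'
#' @param vcf_path path to the VCF file.
#' @param defn a [trisnp_definition()].
#' @return data.frame: `subject_id`, `hap_a`, `hap_b`, `genotype`.
#' @export
call_trisnp_vcf <- function(vcf_path, defn = trisnp_definition()) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    tc4_stop("triC4_dependency", "VariantAnnotation is required to read VCF files")
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(rr)
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)), function(a)
    as.character(a)[1], character(1))
  gt <- VariantAnnotation::geno(vcf)$GT
  site_idx <- match(defn$snp_ids, ids)
  miss <- is.na(site_idx)
  site_idx[miss] <- match(defn$pos[miss], pos)
  if (any(is.na(site_idx)))
    tc4_stop("triC4_missing_site",
             sprintf("tri-SNP site(s) %s absent from VCF",
                     paste(defn$snp_ids[is.na(site_idx)], collapse = ", ")))
  samples <- colnames(gt)
  out <- lapply(samples, function(s) {
    pairs <- vector("list", 3L)
    phased <- TRUE
    for (k in 1:3) {
      g <- gt[site_idx[k], s]
      if (is.na(g) || g %in% c(".", "./.", ".|."))
        tc4_stop("triC4_missing_site",
                 sprintf("missing genotype for sample %s at %s", s, defn$snp_ids[k]))
      sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
      if (sep == "/") phased <- FALSE
      al <- as.integer(strsplit(g, sep, fixed = TRUE)[[1]])
      pairs[[k]] <- ifelse(al == 0L, ref[site_idx[k]], alt[site_idx[k]])
    }
    g <- call_trisnp(pairs, defn, phased = phased)
    data.frame(subject_id = s, hap_a = g$hapA, hap_b = g$hapB,
               genotype = g$genotype, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Impute B8-DR3 dosage for every sample in a VCF
#'
#' Extracts the tag-SNP panel sites (by ID prefix or an explicit ID vector),
#' counts alternate alleles per sample and site, and applies
#' [impute_b8_dosage()].
#'
#' @param vcf_path path to the VCF file.
#' @param panel_ids character vector of panel site IDs; by default every site
#'   whose ID starts with `"b8_"` (the fixture writer's convention).
#' @return data.frame: `subject_id`, `b8_dosage`, `n_sites_used`, `tie`.
#' @export
impute_b8_vcf <- function(vcf_path, panel_ids = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    tc4_stop("triC4_dependency", "VariantAnnotation is required to read VCF files")
  vcf <- VariantAnnotation::readVcf(vcf_path)
  ids <- names(SummarizedExperiment::rowRanges(vcf))
  if (is.null(panel_ids)) panel_ids <- ids[startsWith(ids, "b8_")]
  idx <- match(panel_ids, ids)
  if (all(is.na(idx))) tc4_stop("triC4_no_data", "no B8 panel sites found in VCF")
  gt <- VariantAnnotation::geno(vcf)$GT[idx[!is.na(idx)], , drop = FALSE]
  counts <- apply(gt, 2, function(g) {
    vapply(g, function(x) {
      if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
      sum(as.integer(strsplit(x, "[|/]")[[1]]))
    }, integer(1))
  })
  out <- suppressWarnings(lapply(colnames(gt), function(s) {
    d <- impute_b8_dosage(counts[, s])
    data.frame(subject_id = s, b8_dosage = d$dosage,
               n_sites_used = d$n_sites_used, tie = d$tie,
               stringsAsFactors = FALSE)
  }))
  do.call(rbind, out)
}
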