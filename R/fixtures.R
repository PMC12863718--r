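#' Write a complete synthetic fixture bundle
#'
#' Simulates a cohort under `config` + `seed` and writes every input the
#' pipeline consumes: a phased VCF with the three tri-SNP sites and the B8
#' tag-SNP panel, a subject metadata TSV (covariates, outcome times/flags
#' and simulation truths), the 1 kb window BED, a long-format windowed
#' coverage TSV for the WGS subset (both MAPQ classes), an RNA count TSV
#' with its sample-covariate TSV, and a JSON manifest recording the config
#' and seed. Identical config + seed give a byte-identical bundle.
#'
#' @param config a [sim_config()]. Coverage is simulated for the first
#'   `config$coverage$n_wgs` DR3/DR3 subjects; expression for
#'   `config$expression$n_individuals` DR3/DR3 subjects.
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @param region_config a [c4_region_config()] for the coverage geometry.
#' @return (invisibly) list with the simulated objects (`cohort`,
#'   `coverage`, `expression`, `wgs_ids`) and `files`, the named vector of
#'   written paths.
#' @export
write_fixture_bundle <- function(config, seed, out_dir,
                                 region_config = c4_region_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    tc4_stop("triC4_io", sprintf("cannot create output directory '%s'", out_dir))
  cohort <- simulate_cohort(config, seed)
  dr3 <- cohort[cohort$hla == "DR3/DR3", ]
  n_wgs <- min(config$coverage$n_wgs, nrow(dr3))
  wgs <- dr3[seq_len(n_wgs), ]
  cov <- simulate_coverage(wgs, config, seed, region_config)
  n_expr <- min(config$expression$n_individuals, nrow(dr3))
  expr_ind <- dr3[seq_len(n_expr), ]
  es <- simulate_expression(config, seed,
                            dosage = setNames(expr_ind$trisnp_dosage,
                                              expr_ind$subject_id))
  files <- c(
    vcf = file.path(out_dir, "cohort.vcf"),
    meta = file.path(out_dir, "meta.tsv"),
    bed = file.path(out_dir, "windows.bed"),
    coverage = file.path(out_dir, "coverage.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    expr_covars = file.path(out_dir, "expr_covars.tsv"),
    manifest = file.path(out_dir, "manifest.json"))

  write_phased_vcf(cohort, attr(cohort, "b8_panel"), files["vcf"])

  meta <- cohort[, setdiff(names(cohort),
                           c("hapA_c4a", "hapA_c4b", "hapB_c4a", "hapB_c4b",
                             "hapA_b8", "hapB_b8"))]
  write.table(meta, files["meta"], sep = "\t", quote = FALSE, row.names = FALSE)

  write.table(cov$windows, files["bed"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  len <- cov$windows$end - cov$windows$start
  long <- do.call(rbind, lapply(seq_along(cov$sample_ids), function(i)
    data.frame(sample_id = cov$sample_ids[i], chrom = cov$windows$chrom,
               start = cov$windows$start, end = cov$windows$end,
               sum_all = round(cov$depth_all[i, ] * len),
               sum_uniq = round(cov$depth_uniq[i, ] * len))))
  write.table(long, files["coverage"], sep = "\t", quote = FALSE, row.names = FALSE)

  counts <- data.frame(gene = rownames(es$counts), es$counts, check.names = FALSE)
  write.table(counts, files["counts"], sep = "\t", quote = FALSE, row.names = FALSE)
  covars <- es$samples
  covars$trisnp_dosage <- es$dosage[covars$individual_id]
  write.table(covars, files["expr_covars"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(seed = seed, n_subjects = config$n_subjects,
                   hw_mode = config$hw_mode,
                   c4 = config$c4[c("p101", "pother")],
                   b8 = config$b8, covariates = config$covariates,
                   coverage = config$coverage, expression = config$expression,
                   surv = list(shape = config$surv$shape,
                               admin_censor = config$surv$admin_censor,
                               dropout_mean = config$surv$dropout_mean,
                               trisnp_hr = vapply(config$surv$streams,
                                                  function(s) s$trisnp_hr,
                                                  numeric(1)),
                               targets = vapply(config$surv$streams,
                                                function(s) s$target, numeric(1))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), files["manifest"])
  invisible(list(cohort = cohort, coverage = cov, expression = es,
                 wgs_ids = wgs$subject_id, files = files))
}

# phased VCF writer: 3 tri-SNP sites + B8 tag panel, GT-only, hg38-style
# header. Plain text; consumed back via VariantAnnotation in call_trisnp_vcf.
write_phased_vcf <- function(cohort, b8_panel, path,
                             defn = trisnp_definition()) {
  n <- nrow(cohort)
  ps <- ncol(b8_panel$hapA)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triC4-synthetic",
    "##contig=<ID=chr6,length=170805979>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$subject_id), collapse = "\t"))
  site_rows <- character(3 + ps)
  for (k in 1:3) {
    codesA <- substr(cohort$hapA_trisnp, k, k)
    codesB <- substr(cohort$hapB_trisnp, k, k)
    gt <- paste0(codesA, "|", codesB)
    site_rows[k] <- paste(c(defn$chrom, defn$pos[k], defn$snp_ids[k],
                            defn$ref[k], defn$alt[k], ".", "PASS", ".", "GT", gt),
                          collapse = "\t")
  }
  panel_pos <- 29900000L + seq_len(ps) * 10000L
  for (j in seq_len(ps)) {
    gt <- paste0(b8_panel$hapA[, j], "|", b8_panel$hapB[, j])
    site_rows[3 + j] <- paste(c("chr6", panel_pos[j], sprintf("b8_%03d", j),
                                "A", "G", ".", "PASS", ".", "GT", gt),
                              collapse = "\t")
  }
  writeLines(c(header, site_rows), path)
}

#' Read a fixture metadata TSV
#'
#' @param path path to `meta.tsv` as written by [write_fixture_bundle()].
#' @return data.frame.
#' @export
read_meta_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
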