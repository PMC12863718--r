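#' Published HLA-by-tri-SNP genotype cross-tabulation
#'
#' Genotype counts from the TEDDY birth cohort (7759 HLA- and tri-SNP-typed
#' children): rows are HLA class II genotypes, columns tri-SNP genotypes
#' (lexicographically ordered haplotype pairs over the binary tri-SNP code).
#' Used as the default haplotype-frequency source for the synthetic-cohort
#' generator and as the input for chromosome-level haplotype accounting.
#'
#' @return A [contingency_table] of subject counts (10 HLA rows, 11 tri-SNP
#'   genotype columns).
#' @export
ref_hla_trisnp_table <- function() {
  cols <- c("010/010", "010/101", "101/101", "000/010", "001/010", "000/101",
            "000/000", "000/001", "001/101", "011/101", "010/011")
  rows <- c("DR3/DR3", "DR3/DR4", "DR4/DR4", "DR4/DR8", "DR1/DR4", "DR4/DR13",
            "DR3/DR9", "DR4/DR9", "DR4/DR4*030X/020X", "DR4/DR4*030X/0304")
  counts <- rbind(
    c(  62,  348, 1177,   13,   2, 11, 0, 0, 2, 1, 0),
    c( 408, 2550,    3,   19,   8, 30, 0, 1, 1, 1, 1),
    c(1480,    5,    3,   39,   3,  1, 0, 0, 0, 0, 0),
    c(  14,    0,    0, 1297,   5,  0,17, 1, 0, 0, 0),
    c(   0,    0,    0,   15, 143,  0, 0, 2, 0, 0, 0),
    c(   0,    0,    0,    0,  56,  0, 0, 1, 0, 0, 0),
    c(   2,   16,    0,    0,   0,  0, 0, 0, 0, 0, 0),
    c(  13,    1,    0,    0,   0,  0, 0, 0, 0, 0, 0),
    c(   4,    0,    0,    0,   0,  0, 0, 0, 0, 0, 0),
    c(   3,    0,    0,    0,   0,  0, 0, 0, 0, 0, 0))
  contingency_table(counts, rows, cols)
}

#' Published C4 copy-number by tri-SNP 101 dosage cross-tabulations
#'
#' Estimated C4A (`ref_c4a_dosage_table`) and C4B (`ref_c4b_dosage_table`)
#' gene copy numbers against the number of tri-SNP 101 alleles in 188
#' whole-genome-sequenced DR3-DQ2 homozygous individuals. Rows are gene copy
#' number (0-3), columns 101 allele dosage (0, 1, 2).
#'
#' @return A [contingency_table] (4 rows, 3 columns).
#' @export
ref_c4a_dosage_table <- function() {
  contingency_table(rbind(c(0, 0, 107), c(0, 44, 10), c(9, 9, 7), c(1, 0, 1)),
                    row_labels = as.character(0:3), col_labels = as.character(0:2))
}

#' @rdname ref_c4a_dosage_table
#' @export
ref_c4b_dosage_table <- function() {
  contingency_table(rbind(c(1, 0, 0), c(5, 34, 4), c(4, 17, 119), c(0, 2, 2)),
                    row_labels = as.character(0:3), col_labels = as.character(0:2))
}

#' Cohort endpoint totals
#'
#' Event counts and analysis-set sizes for the six study endpoints in the
#' HLA-eligible cohort after removal of under-sized categories, as published.
#' These marginal event fractions are the calibration targets of the
#' synthetic outcome generator.
#'
#' @return data.frame with columns `endpoint`, `events`, `total`.
#' @export
ref_endpoint_totals <- function() {
  data.frame(
    endpoint = c("T1D", "IA", "IAA_first", "GADA_first", "CD", "CDA"),
    events   = c(397L, 858L, 313L, 382L, 617L, 1294L),
    total    = c(7703L, 7703L, 7703L, 7703L, 7703L, 6709L))
}

#' GWAS covariate panel
#'
#' Previously published GWAS SNPs used as numeric (0/1/2 alternate-allele
#' dosage) covariates in the proportional-hazards models, with per-endpoint
#' inclusion flags and the hazard ratios reported for the endpoints they were
#' associated with. Endpoint columns follow the convention that the
#' first-appearing-autoantibody models reuse the islet-autoimmunity (IA) set.
#'
#' @return data.frame with columns `snp`, `locus`, logical `cd`, `cda`,
#'   `t1d`, `ia`, and numeric `hr_cd`, `hr_cda`, `hr_t1d`, `hr_ia` (NA where
#'   the SNP is not in that endpoint's model).
#' @export
ref_gwas_panel <- function() {
  x <- read.delim(text = paste(
    "snp\tlocus\tcd\tcda\tt1d\tia\thr_cd\thr_cda\thr_t1d\thr_ia",
    "rs4851575\tIL18R1\tTRUE\tFALSE\tFALSE\tFALSE\t1.45\tNA\tNA\tNA",
    "rs114569351\tPLEK\tTRUE\tFALSE\tFALSE\tFALSE\t2.64\tNA\tNA\tNA",
    "rs12493471\tCCR9\tTRUE\tFALSE\tFALSE\tFALSE\t1.40\tNA\tNA\tNA",
    "rs1054091\tRSPH3\tTRUE\tFALSE\tFALSE\tFALSE\t1.59\tNA\tNA\tNA",
    "rs72704176\tASH1L\tTRUE\tFALSE\tFALSE\tFALSE\t2.26\tNA\tNA\tNA",
    "rs3771689\tBAZ2B\tTRUE\tFALSE\tFALSE\tFALSE\t0.56\tNA\tNA\tNA",
    "rs13014907\tZNF804A\tTRUE\tFALSE\tFALSE\tFALSE\t2.46\tNA\tNA\tNA",
    "rs11739460\tTCOF1\tTRUE\tFALSE\tFALSE\tFALSE\t1.41\tNA\tNA\tNA",
    "rs77532435\tGRB10\tTRUE\tFALSE\tFALSE\tFALSE\t2.05\tNA\tNA\tNA",
    "rs6967298\tAUTS2\tTRUE\tFALSE\tFALSE\tFALSE\t0.61\tNA\tNA\tNA",
    "rs61751041\tLAMB1\tTRUE\tFALSE\tFALSE\tFALSE\t2.23\tNA\tNA\tNA",
    "rs2409747\tXKR6\tTRUE\tTRUE\tFALSE\tFALSE\t1.58\t1.37\tNA\tNA",
    "rs12990970\tCTLA4\tFALSE\tTRUE\tFALSE\tFALSE\tNA\t0.76\tNA\tNA",
    "rs11709472\tLPP\tFALSE\tTRUE\tFALSE\tFALSE\tNA\t0.80\tNA\tNA",
    "rs72717025\tFCGR2A\tFALSE\tTRUE\tFALSE\tFALSE\tNA\t1.84\tNA\tNA",
    "rs114157400\tBANK1\tFALSE\tTRUE\tFALSE\tFALSE\tNA\t1.62\tNA\tNA",
    "rs117561283\tIFNG\tFALSE\tTRUE\tFALSE\tFALSE\tNA\t1.81\tNA\tNA",
    "rs8013918\tFOS\tFALSE\tTRUE\tFALSE\tFALSE\tNA\t0.80\tNA\tNA",
    "rs73043122\tRNASET2\tFALSE\tFALSE\tTRUE\tFALSE\tNA\tNA\t3.35\tNA",
    "rs113306148\tPLEKHA1\tFALSE\tFALSE\tTRUE\tFALSE\tNA\tNA\t3.06\tNA",
    "rs428595\tPPIL2\tFALSE\tFALSE\tTRUE\tTRUE\tNA\tNA\t3.42\t2.46",
    "rs1004446\tINS\tFALSE\tFALSE\tTRUE\tTRUE\tNA\tNA\t0.55\t0.67",
    "rs2476601\tPTPN22\tFALSE\tFALSE\tTRUE\tTRUE\tNA\tNA\t1.91\t1.73",
    "rs2292239\tERBB3\tFALSE\tFALSE\tTRUE\tTRUE\tNA\tNA\t1.68\t1.45",
    "rs3184504\tSH2B3\tFALSE\tFALSE\tFALSE\tTRUE\tNA\tNA\tNA\t1.40",
    "rs9934817\tRBFOX1\tFALSE\tFALSE\tFALSE\tTRUE\tNA\tNA\tNA\t2.66",
    "rs11705721\tPXK\tFALSE\tFALSE\tFALSE\tTRUE\tNA\tNA\tNA\t1.41",
    sep = "\n"))
  x$cd <- as.logical(x$cd); x$cda <- as.logical(x$cda)
  x$t1d <- as.logical(x$t1d); x$ia <- as.logical(x$ia)
  x
}

#' Published tri-SNP 101 hazard ratios
#'
#' Per-allele hazard ratios of the tri-SNP 101 haplotype reported for each
#' endpoint, in the full cohort and restricted to DR3-DQ2 homozygotes. These
#' parameterize the default effect sizes of the synthetic outcome generator
#' (full-cohort column) and the documentation of the restricted analyses.
#'
#' @return data.frame with columns `endpoint`, `scope`, `hr`, `ci_low`,
#'   `ci_high`.
#' @export
ref_trisnp_hazard_ratios <- function() {
  data.frame(
    endpoint = rep(c("T1D", "IA", "IAA_first", "GADA_first", "CD", "CDA"), each = 2),
    scope = rep(c("all", "DR3_homozygous"), 6),
    hr      = c(0.54, 0.35, 0.71, 0.58, 0.64, 0.48, 0.87, 0.71, 1.32, 1.32, 1.23, 1.23),
    ci_low  = c(0.41, 0.22, 0.58, 0.42, 0.45, 0.25, 0.64, 0.47, 1.06, 1.02, 1.06, 1.02),
    ci_high = c(0.72, 0.56, 0.87, 0.80, 0.91, 0.91, 1.17, 1.07, 1.64, 1.70, 1.44, 1.48))
}
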