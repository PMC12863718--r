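#' Tri-SNP site definition
#'
#' The three HLA-DRA intron-1 sites, in fixed order rs3135394, rs9268645,
#' rs3129877, each with its reference and alternate allele. Haplotypes are
#' coded per site as '0' for the reference and '1' for the alternate allele,
#' so with the default alleles the T1D-risk haplotype AGG reads "010" and the
#' T1D-protective/CD-predisposing haplotype GCA reads "101". The ref/alt
#' orientation is configuration: the published encoding is pinned down only
#' by those two exemplars.
#'
#' @param snp_ids character(3) site identifiers.
#' @param ref,alt character(3) reference/alternate nucleotides per site.
#' @param chrom,pos chromosome and positions used when locating the sites in
#'   a VCF by coordinate and when writing fixtures (defaults are placeholder
#'   coordinates inside HLA-DRA intron 1; override with build-exact values
#'   when available).
#' @return list of class `trisnp_definition`.
#' @export
trisnp_definition <- function(snp_ids = c("rs3135394", "rs9268645", "rs3129877"),
                              ref = c("A", "C", "G"),
                              alt = c("G", "G", "A"),
                              chrom = "chr6",
                              pos = c(32440500L, 32440620L, 32440690L)) {
  stopifnot(length(snp_ids) == 3L, length(ref) == 3L, length(alt) == 3L,
            length(pos) == 3L)
  if (any(ref == alt))
    tc4_stop("triC4_config", "ref and alt alleles must differ at every site")
  structure(list(snp_ids = snp_ids, ref = toupper(ref), alt = toupper(alt),
                 chrom = chrom, pos = as.integer(pos)),
            class = "trisnp_definition")
}

#' Call a tri-SNP genotype from phased allele pairs
#'
#' Encodes each chromosome's nucleotides as a 3-character binary haplotype
#' code ('0' reference, '1' alternate) in the fixed site order. Input is one
#' allele pair per site; the first allele of every pair belongs to one
#' chromosome, the second to the other (phased input). Unphased input is
#' accepted only when it is resolvable, i.e. heterozygous at no more than one
#' of the three sites.
#'
#' @param gt_pairs list of 3 length-2 character vectors (or a 3 x 2 character
#'   matrix): the two alleles at each site.
#' @param defn a [trisnp_definition()].
#' @param phased is the input phased? If FALSE, heterozygosity at two or more
#'   sites is a phasing error.
#' @return list of class `trisnp_genotype` with `hapA`, `hapB` (as given
#'   phase order) and `genotype`, the order-invariant "x/y" display with
#'   lexicographically smaller haplotype first.
#' @export
call_trisnp <- function(gt_pairs, defn = trisnp_definition(), phased = TRUE) {
  if (is.matrix(gt_pairs)) gt_pairs <- split(gt_pairs, row(gt_pairs))
  if (length(gt_pairs) != 3L)
    tc4_stop("triC4_missing_site", "exactly 3 tri-SNP sites are required")
  alleles <- lapply(gt_pairs, function(p) {
    if (length(p) != 2L || any(is.na(p)) || any(p == "."))
      tc4_stop("triC4_missing_site", "missing or incomplete genotype at a tri-SNP site")
    toupper(p)
  })
  code <- vapply(seq_len(3L), function(i) {
    a <- alleles[[i]]
    ok <- a %in% c(defn$ref[i], defn$alt[i])
    if (!all(ok))
      tc4_stop("triC4_allele_mismatch",
               sprintf("allele '%s' at %s is neither ref (%s) nor alt (%s)",
                       a[!ok][1], defn$snp_ids[i], defn$ref[i], defn$alt[i]))
    as.integer(a == defn$alt[i])
  }, integer(2))           # 2 x 3: rows = chromosomes, cols = sites
  if (!phased) {
    n_het <- sum(code[1, ] != code[2, ])
    if (n_het >= 2L)
      tc4_stop("triC4_phasing",
               "unphased genotype heterozygous at 2+ tri-SNP sites cannot be resolved")
  }
  hapA <- paste(code[1, ], collapse = "")
  hapB <- paste(code[2, ], collapse = "")
  sorted <- sort(c(hapA, hapB))
  structure(list(hapA = hapA, hapB = hapB,
                 genotype = paste(sorted, collapse = "/")),
            class = "trisnp_genotype")
}

#' Decode a tri-SNP haplotype code back to nucleotides
#'
#' Inverse of the encoding applied by [call_trisnp()]; used by the fixture
#' writer and the round-trip tests.
#'
#' @param code character: 3-character string over 0/1.
#' @param defn a [trisnp_definition()].
#' @return character(3) nucleotides.
#' @export
decode_trisnp <- function(code, defn = trisnp_definition()) {
  bits <- as.integer(strsplit(code, "")[[1]])
  if (length(bits) != 3L || !all(bits %in% 0:1))
    tc4_stop("triC4_label", "haplotype code must be 3 characters over {0,1}")
  ifelse(bits == 1L, defn$alt, defn$ref)
}

#' Impute B8-DR3 dosage from a tag-SNP panel
#'
#' The extended B8-DR3 haplotype dosage of an individual is taken as the mode
#' of the alternate-allele counts across the panel sites: 0 if most sites are
#' homozygous reference, 1 if most are heterozygous, 2 if most are homozygous
#' alternate. Missing sites (NA) are excluded. When two counts are equally
#' modal the smaller dosage is returned and flagged (conservative call,
#' surfaced for audit).
#'
#' @param alt_allele_counts integer vector over panel sites, values 0/1/2,
#'   NA allowed.
#' @return list of class `b8_dosage`: `dosage`, `n_sites_used`, `tie`
#'   (logical).
#' @export
impute_b8_dosage <- function(alt_allele_counts) {
  x <- alt_allele_counts[!is.na(alt_allele_counts)]
  if (length(x) == 0L)
    tc4_stop("triC4_no_data", "no non-missing panel sites")
  if (!all(x %in% 0:2))
    tc4_stop("triC4_bad_counts", "allele counts must be 0, 1 or 2")
  tab <- tabulate(x + 1L, nbins = 3L)
  top <- which(tab == max(tab))
  tie <- length(top) > 1L
  if (tie) tc4_warn("triC4_b8_tie",
                    "tied modal allele counts; returning the smaller dosage")
  structure(list(dosage = top[1L] - 1L, n_sites_used = length(x), tie = tie),
            class = "b8_dosage")
}

#' Cross-tabulate HLA genotypes against tri-SNP genotypes
#'
#' @param hla character vector of HLA genotype labels (e.g. "DR3/DR4").
#' @param trisnp character vector of tri-SNP genotype strings ("010/101") or
#'   a list of [call_trisnp()] results.
#' @param hla_levels,trisnp_levels optional label orderings; defaults to the
#'   order of first appearance.
#' @return [contingency_table] of subject counts; cells sum to the roster
#'   size (empty rosters give a 0 x 0 table).
#' @export
crosstab_hla_trisnp <- function(hla, trisnp, hla_levels = NULL, trisnp_levels = NULL) {
  if (is.list(trisnp))
    trisnp <- vapply(trisnp, function(g) g$genotype, character(1))
  if (length(hla) != length(trisnp))
    tc4_stop("triC4_bad_counts", "hla and trisnp vectors must have equal length")
  if (is.null(hla_levels)) hla_levels <- unique(hla)
  if (is.null(trisnp_levels)) trisnp_levels <- unique(trisnp)
  m <- table(factor(hla, levels = hla_levels), factor(trisnp, levels = trisnp_levels))
  contingency_table(matrix(as.integer(m), nrow = length(hla_levels),
                           dimnames = list(hla_levels, trisnp_levels)))
}

#' Split a genotype label into its two chromosome labels
#'
#' Plain labels split at the first "/" ("DR3/DR4" -> DR3, DR4). Starred DR4
#' subtype labels ("DR4/DR4*030X/020X") decompose as two DR4-class
#' chromosomes; the subtype qualifier is dropped for chromosome accounting.
#'
#' @param label character(1) genotype label.
#' @return character(2) chromosome labels.
#' @export
parse_genotype_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || !grepl("/", label, fixed = TRUE))
    tc4_stop("triC4_label_parse", sprintf("cannot decompose genotype label '%s'", label))
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  a <- parts[1]
  b <- paste(parts[-1], collapse = "/")
  # starred subtype labels: everything after "*" qualifies the second chromosome
  b <- sub("\\*.*$", "", b)
  if (!nzchar(a) || !nzchar(b))
    tc4_stop("triC4_label_parse", sprintf("cannot decompose genotype label '%s'", label))
  c(a, b)
}

# chromosome counts of haplotype labels among a set of (genotype label, n) rows
count_chromosomes <- function(labels, counts, query) {
  total <- 2L * sum(counts)
  hit <- 0L
  for (i in seq_along(labels)) {
    if (counts[i] == 0) next
    pair <- parse_genotype_label(labels[i])
    hit <- hit + unname(counts[i]) * sum(pair %in% query)
  }
  c(count = unname(hit), total_chromosomes = unname(total))
}

#' Chromosome-level haplotype counts within one HLA genotype row
#'
#' Each subject contributes two chromosomes; a tri-SNP genotype "x/y"
#' contributes one chromosome to x and one to y (two to x when x == y).
#' Restricting a published cross-tab to its DR3/DR3 row and querying
#' \{"101"\} reproduces the "84% (2716/3232) of chromosomes from DR3
#' homozygous individuals had 101" style of accounting.
#'
#' @param table [contingency_table] with HLA rows and tri-SNP genotype
#'   columns (as from [crosstab_hla_trisnp()]).
#' @param hla_genotype row label selecting the scope.
#' @param query character vector of tri-SNP haplotype codes to count.
#' @return named numeric: `count`, `total_chromosomes`.
#' @export
chromosome_haplotype_counts <- function(table, hla_genotype, query) {
  m <- as.matrix(table)
  i <- match(hla_genotype, rownames(m))
  if (is.na(i)) tc4_stop("triC4_label", sprintf("no HLA row '%s'", hla_genotype))
  count_chromosomes(colnames(m), m[i, ], query)
}

#' Chromosome-level HLA haplotype counts within one tri-SNP genotype column
#'
#' Counts chromosomes bearing a given HLA haplotype among all subjects with
#' the given tri-SNP genotype: e.g. DR3 chromosomes among 101/101 homozygotes
#' (published: 2357 of 2366).
#'
#' @param table [contingency_table] with HLA rows and tri-SNP columns.
#' @param trisnp_genotype column label (e.g. "101/101").
#' @param hla_haplotype HLA chromosome label to count (e.g. "DR3").
#' @return named numeric: `count`, `total_chromosomes` (0, 0 when the column
#'   has no subjects).
#' @export
chromosomes_by_hla_within_trisnp <- function(table, trisnp_genotype, hla_haplotype) {
  m <- as.matrix(table)
  j <- match(trisnp_genotype, colnames(m))
  if (is.na(j)) tc4_stop("triC4_label", sprintf("no tri-SNP column '%s'", trisnp_genotype))
  count_chromosomes(rownames(m), m[, j], hla_haplotype)
}

#' Rebuild a subject roster from a contingency table
#'
#' Expands a table of counts back into per-subject (row label, column label)
#' pairs; the inverse of [crosstab_hla_trisnp()] up to subject order. Used to
#' drive chromosome accounting and tests from published tables.
#'
#' @param table [contingency_table].
#' @return data.frame with columns `hla`, `trisnp`.
#' @export
roster_from_table <- function(table) {
  m <- as.matrix(table)
  idx <- which(m > 0, arr.ind = TRUE)
  hla <- rep(rownames(m)[idx[, 1]], m[idx])
  trisnp <- rep(colnames(m)[idx[, 2]], m[idx])
  data.frame(hla = hla, trisnp = trisnp, stringsAsFactors = FALSE)
}
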