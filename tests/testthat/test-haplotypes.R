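test_that("call_trisnp encodes the canonical haplotypes", {
  # AGG ('010') / GCA ('101') heterozygote, the study's key genotype
  g <- call_trisnp(list(c("A", "G"), c("G", "C"), c("G", "A")))
  expect_equal(g$hapA, "010")
  expect_equal(g$hapB, "101")
  expect_equal(g$genotype, "010/101")
  # all-reference and 101-homozygote
  expect_equal(call_trisnp(list(c("A", "A"), c("C", "C"), c("G", "G")))$genotype,
               "000/000")
  expect_equal(call_trisnp(list(c("G", "G"), c("C", "C"), c("A", "A")))$genotype,
               "101/101")
  # display is order-invariant
  g2 <- call_trisnp(list(c("G", "A"), c("C", "G"), c("A", "G")))
  expect_equal(g2$genotype, g$genotype)
})

test_that("call_trisnp rejects bad input with classed errors", {
  expect_error(call_trisnp(list(c("A", "G"), c("G", "C"))),
               class = "triC4_missing_site")
  expect_error(call_trisnp(list(c("A", "G"), c("G", "C"), c(".", "A"))),
               class = "triC4_missing_site")
  expect_error(call_trisnp(list(c("A", "T"), c("G", "C"), c("G", "A"))),
               class = "triC4_allele_mismatch")
  # unphased double-het is ambiguous; unphased hom-resolvable is fine
  expect_error(call_trisnp(list(c("A", "G"), c("G", "C"), c("G", "G")),
                           phased = FALSE),
               class = "triC4_phasing")
  ok <- call_trisnp(list(c("A", "G"), c("C", "C"), c("G", "G")), phased = FALSE)
  expect_equal(ok$genotype, "000/100")
})

test_that("encode/decode round-trips every haplotype", {
  defn <- trisnp_definition()
  codes <- apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = "")
  for (a in codes) for (b in codes) {
    nt <- Map(c, decode_trisnp(a, defn), decode_trisnp(b, defn))
    g <- call_trisnp(nt, defn)
    expect_setequal(c(g$hapA, g$hapB), unique(c(a, b)))
    expect_equal(g$genotype, paste(sort(c(a, b)), collapse = "/"))
  }
})

test_that("impute_b8_dosage is the mode, with audited ties", {
  expect_equal(impute_b8_dosage(c(0, 0, 0, 0, 1))$dosage, 0)
  expect_equal(impute_b8_dosage(c(1, 1, 1, 2, 0))$dosage, 1)
  # brute-force frequency count: 2 appears 4x, 1 once, 0 once
  expect_equal(impute_b8_dosage(c(2, 2, 1, 2, 0, 2))$dosage, 2)
  # NA sites excluded from the mode and the count
  r <- impute_b8_dosage(c(NA, 2, 2, NA, 1))
  expect_equal(r$dosage, 2)
  expect_equal(r$n_sites_used, 3)
  # ties resolve to the smaller dosage, flagged and warned
  expect_warning(r <- impute_b8_dosage(c(0, 0, 2, 2)), class = "triC4_b8_tie")
  expect_equal(r$dosage, 0)
  expect_true(r$tie)
  expect_error(impute_b8_dosage(c(NA, NA)), class = "triC4_no_data")
  expect_error(impute_b8_dosage(c(1, 3)), class = "triC4_bad_counts")
})

test_that("impute_b8_dosage is permutation-invariant", {
  set.seed(42)
  for (i in 1:20) {
    x <- sample(0:2, sample(3:30, 1), replace = TRUE)
    r1 <- suppressWarnings(impute_b8_dosage(x))
    r2 <- suppressWarnings(impute_b8_dosage(sample(x)))
    expect_equal(r1$dosage, r2$dosage)
  }
})

test_that("crosstab conserves the roster and reproduces published margins", {
  hla <- c(rep("DR3/DR3", 4), rep("DR3/DR4", 6))
  tg <- c(rep("101/101", 3), "010/101", rep("010/101", 5), "010/010")
  tab <- crosstab_hla_trisnp(hla, tg)
  expect_equal(sum(tab), 10)
  expect_equal(unname(unclass(tab)["DR3/DR3", "101/101"]), 3)
  # empty roster: all-zero (0-cell) table
  expect_equal(sum(crosstab_hla_trisnp(character(0), character(0))), 0)
  # regenerating the roster from the published table is a fixed point
  ref <- ref_hla_trisnp_table()
  roster <- roster_from_table(ref)
  back <- crosstab_hla_trisnp(roster$hla, roster$trisnp,
                              hla_levels = rownames(ref),
                              trisnp_levels = colnames(ref))
  expect_equal(unclass(back), unclass(ref))
  expect_equal(sum(back["DR3/DR3", ]), 1616)
})

test_that("chromosome accounting reproduces the published proportions", {
  tab <- ref_hla_trisnp_table()
  expect_equal(chromosome_haplotype_counts(tab, "DR3/DR3", "101"),
               c(count = 2716, total_chromosomes = 3232))
  expect_equal(chromosome_haplotype_counts(tab, "DR3/DR3", c("010", "101")),
               c(count = 3203, total_chromosomes = 3232))
  expect_equal(chromosome_haplotype_counts(tab, "DR4/DR4", "010"),
               c(count = 3007, total_chromosomes = 3062))
  expect_equal(chromosomes_by_hla_within_trisnp(tab, "101/101", "DR3"),
               c(count = 2357, total_chromosomes = 2366))
  # brute-force chromosome enumeration over the 101/101 column gives DR4 = 9
  expect_equal(chromosomes_by_hla_within_trisnp(tab, "101/101", "DR4")[["count"]], 9)
})

test_that("chromosome accounting is complete and handles edge cases", {
  tab <- ref_hla_trisnp_table()
  all_codes <- unique(unlist(lapply(colnames(tab), parse_genotype_label)))
  full <- chromosome_haplotype_counts(tab, "DR3/DR4", all_codes)
  expect_equal(full[["count"]], full[["total_chromosomes"]])
  # a single 101/101 subject contributes 2 chromosomes to 101
  one <- crosstab_hla_trisnp("DR3/DR3", "101/101")
  expect_equal(chromosome_haplotype_counts(one, "DR3/DR3", "101"),
               c(count = 2, total_chromosomes = 2))
  # zero-subject scope
  z <- contingency_table(matrix(0, 1, 1), "DR3/DR3", "101/101")
  expect_equal(chromosomes_by_hla_within_trisnp(z, "101/101", "DR3"),
               c(count = 0, total_chromosomes = 0))
  expect_error(parse_genotype_label("DR3"), class = "triC4_label_parse")
  # starred DR4 subtype labels decompose as two DR4-class chromosomes
  expect_equal(parse_genotype_label("DR4/DR4*030X/020X"), c("DR4", "DR4"))
})

test_that("VCF round trip through an external parser preserves the calls", {
  skip_if_not_installed("VariantAnnotation")
  cfg <- small_config(n = 40)
  dir <- withr::local_tempdir()
  bundle <- write_fixture_bundle(cfg, seed = 5, out_dir = dir)
  calls <- call_trisnp_vcf(bundle$files[["vcf"]])
  meta <- read_meta_tsv(bundle$files[["meta"]])
  m <- merge(calls, meta, by = "subject_id")
  expect_equal(m$genotype, m$trisnp)
  b8 <- impute_b8_vcf(bundle$files[["vcf"]])
  m2 <- merge(b8, meta, by = "subject_id")
  # tag panel is noisy by design; imputed dosage matches truth for nearly all
  expect_gte(mean(m2$b8_dosage.x == m2$b8_dosage.y), 0.95)
})
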