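test_that("sample_genotypes reproduces the ascertained genotype distribution", {
  cfg <- small_config(n = 10000)
  geno <- sample_genotypes(cfg, seed = 101)
  expect_lt(abs(mean(geno$hla == "DR3/DR3") - 0.208), 0.015)
  # per-chromosome C4 structure constraint: 1 or 2 modules per chromosome
  expect_true(all(geno$hapA_c4a + geno$hapA_c4b %in% 1:2))
  expect_true(all(geno$total_gcn %in% 2:4))
  expect_equal(geno$gcn_a + geno$gcn_b, geno$total_gcn)
  # determinism under the master seed
  geno2 <- sample_genotypes(cfg, seed = 101)
  expect_identical(geno, geno2)
  expect_false(identical(geno, sample_genotypes(cfg, seed = 102)))
})

test_that("degenerate single-haplotype config gives homozygotes", {
  tab <- contingency_table(matrix(10, 1, 1), "DR3/DR3", "101/101")
  cfg <- sim_config(n_subjects = 50, table1 = tab)
  geno <- sample_genotypes(cfg, seed = 1)
  expect_true(all(geno$trisnp == "101/101"))
  expect_true(all(geno$hla == "DR3/DR3"))
})

test_that("haplotype frequencies converge under Hardy-Weinberg draws", {
  cfg <- sim_config(n_subjects = 100000, hw_mode = "hw")
  geno <- sample_genotypes(cfg, seed = 5)
  hap <- cfg$trisnp_cond$haplotypes
  freq_101_dr3 <- hap$freq[hap$hla == "DR3" & hap$code == "101"]
  obs <- (sum(geno$hapA_hla == "DR3" & geno$hapA_trisnp == "101") +
          sum(geno$hapB_hla == "DR3" & geno$hapB_trisnp == "101")) /
    (2 * nrow(geno))
  expect_equal(obs, freq_101_dr3, tolerance = 0.02)
})

test_that("simulated coverage carries the stated C4 signal", {
  cfg <- small_config(n = 2000)
  geno <- sample_genotypes(cfg, seed = 61)
  # the WGS arm of the study is DR3/DR3-only; C4A deletions concentrate there
  geno <- geno[geno$hla == "DR3/DR3", ][1:300, ]
  cs <- simulate_coverage(geno, cfg, seed = 61)
  calls <- call_c4(cs)
  # expected diploid-scale means by construction
  expect_equal(mean(calls$c4_norm_all[geno$total_gcn == 2]), 1.0, tolerance = 0.03)
  expect_equal(mean(calls$c4_norm_all[geno$total_gcn == 3]), 1.5, tolerance = 0.03)
  one_a <- geno$gcn_a == 1
  expect_equal(mean(calls$uniq_a[one_a]), 0.3, tolerance = 0.03)
  # C4A-unique histogram: mass at 0 (deletions) and a peak near 0.3 (1 copy)
  expect_gt(mean(calls$uniq_a < 0.04), 0.2)
  expect_gt(mean(abs(calls$uniq_a - 0.3) < 0.1), 0.15)
  # C4A-null samples concentrate in 101/101 homozygotes
  expect_gt(mean(geno$trisnp_dosage[calls$gcn_a == 0] == 2), 0.95)
})

test_that("null outcome model is exchangeable and targets are hit", {
  # all hazard ratios 1: logrank-style comparison should be unremarkable
  null_streams <- lapply(triC4:::sim_survival_defaults()$streams, function(s) {
    s$trisnp_hr <- 1; s$hla_hr <- s$hla_hr * 0 + 1; s$male_hr <- 1
    s$fdr_hr <- 1; s$country_hr <- NULL; s$ancestry_hr <- NULL
    s$gwas_hr <- NULL; s$gluten_hr <- 1; s
  })
  cfg <- sim_config(n_subjects = 3000, surv = list(streams = null_streams))
  co <- simulate_cohort(cfg, seed = 71)
  sd <- survival::survdiff(survival::Surv(t1d_time, t1d_event) ~ trisnp_dosage,
                           data = co)
  expect_gt(1 - pchisq(sd$chisq, length(sd$n) - 1), 0.001)
  # event fraction lands near the published 5.2% for T1D
  cfg2 <- small_config(n = 7703)
  co2 <- simulate_cohort(cfg2, seed = 72)
  expect_equal(mean(co2$t1d_event), 397 / 7703, tolerance = 0.15)
})

test_that("fixture bundles are reproducible and round-trip the pipeline", {
  skip_if_not_installed("VariantAnnotation")
  cfg <- sim_config(n_subjects = 250,
                    coverage = list(n_wgs = 30L),
                    expression = list(n_individuals = 20L, n_genes = 40L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- write_fixture_bundle(cfg, seed = 9, out_dir = d1)
  b2 <- write_fixture_bundle(cfg, seed = 9, out_dir = d2)
  for (f in names(b1$files))
    expect_identical(readLines(b1$files[[f]]), readLines(b2$files[[f]]),
                     label = paste("file", f))
  # tri-SNP genotypes recovered exactly from the VCF
  calls <- call_trisnp_vcf(b1$files[["vcf"]])
  meta <- read_meta_tsv(b1$files[["meta"]])
  m <- merge(calls, meta, by = "subject_id")
  expect_equal(m$genotype, m$trisnp)
  # coverage TSV + BED round-trips through the C4 caller at >= 99% accuracy
  w <- read.delim(b1$files[["bed"]], header = FALSE,
                  col.names = c("chrom", "start", "end"))
  cs <- read_coverage_tsv(b1$files[["coverage"]], w)
  c4 <- call_c4(cs)
  truth <- meta[match(c4$sample_id, meta$subject_id), ]
  expect_gte(mean(c4$total_gcn == truth$total_gcn), 0.99)
  expect_gte(mean(c4$gcn_a == truth$gcn_a & c4$gcn_b == truth$gcn_b), 0.97)
  # counts round-trip into the trend model
  x <- read.delim(b1$files[["counts"]], check.names = FALSE)
  counts <- as.matrix(x[, -1]); rownames(counts) <- x[[1]]
  cv <- read.delim(b1$files[["expr_covars"]])
  dosage <- setNames(cv$trisnp_dosage[!duplicated(cv$individual_id)],
                     cv$individual_id[!duplicated(cv$individual_id)])
  tr <- dosage_trend(expression_set(counts, cv, dosage))
  expect_equal(nrow(tr), 40)
  # manifest records the seed
  manifest <- jsonlite::fromJSON(b1$files[["manifest"]])
  expect_equal(manifest$seed, 9)
})
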