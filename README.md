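# triC4

Tools for studying the **HLA-DRA intron-1 tri-SNP haplotype** (rs3135394,
rs9268645, rs3129877) and its relationship to **complement C4A/C4B copy
number** and **autoimmune disease outcomes** (type 1 diabetes and celiac
disease) in HLA-selected prospective birth cohorts.

## Who this is for

The tri-SNP is coded per site as 0 = reference / 1 = alternate allele:
haplotype **010** (nucleotides AGG) marks T1D risk, **101** (GCA) is
T1D-protective but celiac-predisposing, and travels almost exclusively on
DR3-DQ2 chromosomes. 101 chromosomes are also enriched for C4A-deleted C4
structural alleles, tying the haplotype to complement biology. Analysts who
want to call this haplotype from phased VCFs, estimate C4A/C4B gene copy
number (GCN) from WGS read depth, test haplotype-dosage/copy-number
association, and fit covariate-adjusted Cox proportional-hazards models for
autoimmune endpoints will find each stage here as a tested, composable
function — together with a synthetic-cohort generator that reproduces the
statistical structure of such a study, because the real cohort data are
controlled-access.

## The core models

* **Haplotype calling** — phased alleles at the three sites map to two
  3-bit codes per subject; chromosome-level accounting treats genotype
  "x/y" as one chromosome of each.
* **C4 copy number** — per-sample windowed depth is normalized so 25 kb
  flanks average 2.0 (diploid). Total C4 GCN g makes the combined C4 region
  read ≈ g/2 (peaks 1, 1.5, 2 ⇒ g = 2, 3, 4; thresholds 1.4 / 1.9), and
  each paralog's ~3 kb discriminating region reads ≈ 0.3 per copy in
  unique-mapping coverage (null below 0.04). The split heuristic: null
  paralog ⇒ other takes the total; g=2 ⇒ 1+1; g=3 ⇒ larger unique coverage
  gets 2; g=4 ⇒ 2+2 unless the coverage ratio exceeds 2.5 (then 3+1).
* **Association** — Pearson chi-squared on R×C GCN-by-dosage tables,
  Σ(O−E)²/E, no continuity correction.
* **Survival** — Cox PH (Efron ties) on age in months with numeric
  per-allele dosages and categorical covariates (baselines DR4/DR8, female,
  US, EUR), category filtering at n ≥ 20 with event/non-event checks,
  endpoint-specific censoring incl. first-autoantibody endotypes.
* **Expression** — CPM → per-individual medians → per-gene OLS of
  log2(CPM+0.5) on batch + age + sex + dosage, BH adjustment.

## Worked example

Association between C4A copy number and tri-SNP 101 dosage, on the
published 188-sample DR3/DR3 WGS cross-tabulation shipped as a reference
table:

```r
library(triC4)
tab <- ref_c4a_dosage_table()
print(tab)
#> Contingency table (4x3, N = 188)
#>      0  1   2 All
#> 0    0  0 107 107
#> 1    0 44  10  54
#> 2    9  9   7  25
#> 3    1  0   1   2
#> All 10 53 125 188
pearson_chisq(tab)
#> Pearson chi-squared: statistic = 188.4, df = 6, p = 5.59e-38
```

The p-value says C4A copy number and 101 dosage are anything but
independent: every one of the 107 C4A-null samples sits in the 101/101
column. Chromosome-level accounting on the cohort genotype table:

```r
cc <- chromosome_haplotype_counts(ref_hla_trisnp_table(), "DR3/DR3", "101")
#> 101 chromosomes among DR3/DR3: 2716/3232 (84.0%)
```

A synthetic cohort exercises the full pipeline — genotypes, outcomes,
coverage, calling, modelling:

```r
cfg <- sim_config(n_subjects = 4000)
cohort <- simulate_cohort(cfg, seed = 2)
fit <- fit_endpoint_model(cohort, cox_model_spec("T1D", "all"))
subset(fit, covariate == "trisnp_dosage")
#>                   covariate log_hr    hr ci95_low ci95_high    se p_value
#> trisnp_dosage trisnp_dosage -0.578 0.561    0.388     0.813 0.189 0.00223
```

The fitted per-allele hazard ratio 0.56 (CI 0.39–0.81) recovers the
generating truth of 0.54: each 101 allele roughly halves T1D hazard. The
copy-number caller round-trips simulated WGS coverage:

```r
dr3 <- cohort[cohort$hla == "DR3/DR3", ][1:188, ]
calls <- call_c4(simulate_coverage(dr3, cfg, seed = 2))
mean(calls$gcn_a == dr3$gcn_a & calls$gcn_b == dr3$gcn_b)
#> [1] 1
```

## Command line

```sh
exec/tric4 simulate --seed 42 --n 500 --out fixtures/
exec/tric4 call-trisnp --vcf fixtures/cohort.vcf --out calls.tsv
exec/tric4 call-c4 --coverage fixtures/coverage.tsv --windows fixtures/windows.bed --out c4.tsv
exec/tric4 associate --calls c4.tsv --meta fixtures/meta.tsv --paralog A --out assoc.json
```

See `vignettes/methods.Rmd` for the models, assumptions, generator design
and known limitations.
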