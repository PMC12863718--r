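---
title: "Models and methods: tri-SNP haplotypes, C4 copy number, and outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triC4)
```

## The scientific problem

Type 1 diabetes (T1D) and celiac disease (CD) share their strongest genetic
risk factor, the HLA class II DR3-DQ2 haplotype. Within DR3-DQ2 carriers,
however, risk is further stratified by a three-SNP haplotype ("tri-SNP":
rs3135394, rs9268645, rs3129877) in intron 1 of *HLA-DRA*. Coding each site
as 0 (reference) / 1 (alternate), the AGG haplotype reads **010** (T1D risk)
and GCA reads **101** (T1D-protective, CD-predisposing). The 101 haplotype
travels almost exclusively on DR3-DQ2 chromosomes and is strongly coupled to
structural variation at the complement *C4* locus: 101 chromosomes are
enriched for C4A-deleted, C4B-carrying structural alleles, so 101/101
homozygotes are frequently C4A null. This package implements the
computational chain connecting those observations: haplotype calling from
phased variants, a read-depth C4 paralog copy-number caller, contingency
association, covariate-adjusted Cox time-to-event models for six autoimmune
endpoints, and an expression dosage-trend screen — plus a synthetic-cohort
generator that makes the whole chain testable without the controlled-access
cohort data.

## Haplotype calling

`call_trisnp()` encodes the two phased alleles at each of the three sites in
fixed site order. The ref/alt orientation per site is configuration
(`trisnp_definition()`), defaulting to (A/G, C/G, G/A) — the only assignment
consistent with both published exemplars (AGG = 010, GCA = 101). Unphased
genotypes heterozygous at two or more sites are rejected rather than
statistically phased: the source data were phased call files, and silent
statistical phasing would manufacture haplotypes. B8-DR3 extended-haplotype
dosage is imputed as the mode of alternate-allele counts over a tag-SNP
panel (`impute_b8_dosage()`); a tie between modes returns the smaller
dosage with an audit flag — the conservative call.

Chromosome-level accounting (`chromosome_haplotype_counts()`) treats every
subject as two chromosomes: genotype "x/y" contributes one chromosome to x
and one to y. Starred DR4 subtype genotype labels decompose as two
DR4-class chromosomes; these rows are removed before modelling anyway by
the category-size filter.

## C4 copy number from windowed depth

Depth is computed over 1 kb non-overlapping windows (BED convention) from
`samtools bedcov`-style summed base coverage, in two MAPQ classes (all
reads; uniquely mapping, MAPQ ≥ 30). Each sample is normalized so its mean
all-read depth over the two 25 kb flanks of the C4 locus equals 2.0
(diploid). The source describes only "average normalized coverage"; flank
normalization is the scheme consistent with both published histogram
descriptions — flanks peaking at 2, and the combined C4 region peaking at
1, 1.5 and 2 for total copy numbers 2, 3 and 4. The factor-of-two geometry
arises because reads from all C4 copies distribute over the two paralogous
reference loci: normalized C4 coverage ≈ total copies / 2.

Total copy number is thresholded at 1.4 and 1.9; the published rule uses
strict inequalities on both sides, leaving exact boundary values undefined,
so boundaries assign to the lower class (deterministic, documented). Values
below 0.7 fall outside the observed peaks; the caller returns 2 with a QC
flag rather than extrapolating outside the published codomain {2, 3, 4}.
The paralog split uses the ~3 kb discriminating regions where C4A and C4B
differ: a paralog below 0.04 mean unique coverage is null and the other
paralog takes the whole total (C4A checked first, as published); otherwise
totals 2/3/4 split 1+1, 2+1 by coverage order (ties to C4A), and 2+2 unless
the coverage ratio exceeds 2.5 (then 3+1). The exact hg38 coordinates of
the discriminating regions, HERV insertion and gene bodies are config
values (`c4_region_config()`) with grid-aligned approximate defaults; the
source gives only approximate descriptions, and nothing downstream depends
on the exact coordinates so long as generator and caller agree.

## Association

`pearson_chisq()` is the plain Pearson R×C statistic without continuity
correction, all-zero rows/columns dropped before computing df. This choice
reproduces the published C4A-by-dosage p-value (5.59E-38) exactly at the
printed precision. Expected counts below 5 raise a warning flag, not an
error — the published tables themselves are sparse. A brute-force O/E
double-loop oracle validates the implementation to relative error < 1e-12
in the test suite. Note: the published C4B-by-dosage p-value (1.89E-20)
does **not** follow from the published C4B table under any chi-squared
variant we tried (Pearson gives 3.17E-20, G-test 4.29E-18, and no
single-sample perturbation of the table yields 1.89E-20); the
corresponding acceptance test asserts the printed value and is expected to
fail, with the value the printed table actually implies frozen alongside.

## Survival models

Age in months is the time axis. Events: T1D and CD diagnosis (censor at
latest clinic visit), islet autoimmunity and celiac autoimmunity (censor at
last negative sample), and the IAA-first/GADA-first endotypes, where the
appearance of a *different* first autoantibody right-censors the subject at
that time. Tri-SNP 101, B8 and GWAS dosages are numeric additive covariates
(hazard ratios per additional allele); HLA genotype, sex, country and
ancestry are categorical with baselines DR4/DR8, female, US and EUR.
First-degree-relative status is disease-specific (T1D relatives for the
islet endpoints, CD relatives for the celiac endpoints), so the cohort
schema carries two flags.

Filtering iterates to a fixed point: complete-case removal, removal of
categorical levels with fewer than 20 members, and removal of levels with
zero events or zero non-events. The source describes the steps but not
their order; the fixed point makes the result order-independent and
idempotent. Partial-likelihood maximization is delegated to
`survival::coxph()` with Efron ties — the module's contribution is the
encoding, censoring and filtering logic plus the simulation-recovery
harness, not a bespoke optimizer.

## Expression trend

Counts per million are computed per sample, aggregated to per-individual
medians (multiple blood draws per child), and each gene's log2(CPM + 0.5)
is regressed on batch, age category (younger/older than 1 year), sex and
numeric tri-SNP dosage by ordinary least squares, with a two-sided t-test
on the dosage coefficient and Benjamini–Hochberg adjustment across genes.
This deliberately replaces the original moderated per-sample analysis with
individual as a blocking factor: median aggregation removes the
within-individual correlation instead, at some cost in power. The offset
0.5 avoids −∞ at zero counts while preserving ordering. Per-individual
covariates are taken from the individual's first sample; batch and age can
vary across a child's samples and a single value must represent them after
aggregation.

## The synthetic cohort: what it emulates and what it does not

The generator's defaults are the stated world of the source cohort:

* **Genotypes.** The HLA genotype row distribution and the per-row tri-SNP
  chromosome frequencies are fitted from the published 7759-subject
  cross-tabulation. Where both the HLA pair and tri-SNP pair are
  heterozygous, the table does not identify phase; the decomposition picks
  the assignment with the higher linkage-affinity score (101→DR3, 010→DR4,
  …), a deterministic heuristic. The default sampling mode draws genotype
  rows directly (matching the HLA-ascertained cohort); a Hardy–Weinberg
  i.i.d. haplotype mode is available but reproduces the ascertained margins
  poorly, which is a property of the real design, not a bug.
* **C4 structures.** Per-chromosome (C4A, C4B) configurations — 1 or 2
  modules per chromosome — conditional on carrying 101, maximum-likelihood
  fitted offline to the six marginal columns of the published copy-number
  tables and frozen as defaults. The joint (C4A, C4B) law is a fitted
  choice; only marginals are published, and the small-n tables are not
  exactly consistent with chromosome-level independence, so a residual
  misfit of a few samples per cell remains.
* **Coverage.** Flank depth ~ Normal(30×, 3×) per sample, per-window
  multiplicative log-normal noise at CV 5% (mean-corrected), all-read C4
  signal = total copies/4 of flank depth, unique-region signal = 0.3 per
  paralog copy — the published per-copy unique peak. The HERV interval is
  attenuated by a long-allele fraction of 0.6. Window noise is
  independent; real WGS has GC-tracking, mappability and insert-size
  structure that this does not emulate, so a green recovery test
  establishes correctness of the calling logic, not robustness to real
  sequencing artefacts.
* **Outcomes.** Weibull proportional hazards (shape 1.3, chosen for rising
  pediatric incidence; the source gives no baseline hazard), linear
  predictor = Σ covariate × log HR with per-allele tri-SNP hazard ratios
  set to the published point estimates (0.54 T1D, 0.64 IAA-first, 0.87
  GADA-first, 1.32 CD, 1.23 CDA), administrative censoring at 180 months
  plus exponential dropout (mean 600 months). The three islet-antibody
  streams (IAA, GADA, other) compete; the earliest defines the endotype.
  Baseline scales are calibrated numerically (midpoint-rule integration +
  root finding, fixed-point over competing streams) so each stream's
  expected observed-event fraction matches the published fraction (e.g.
  5.2% T1D). By default there is **no** tri-SNP × DR3/DR3 interaction, so
  the full-cohort fitted effect has a well-defined truth; the stronger
  DR3-restricted published estimates are reproduced qualitatively by
  configuring an interaction, as the tests demonstrate. HLA hazard ratios
  beyond the published DR3/DR4 values are stylized choices on the right
  order for each disease; they are nuisance structure for the recovery
  properties, not estimands.
* **Expression.** Negative-binomial counts (dispersion 0.3), ~4 samples
  per individual over 129 DR3/DR3 individuals, C4A-like effect −1
  log2/allele and C4B-like +0.5 (signs as published; magnitudes chosen to
  give the published significance ordering), batch/age/sex nuisance
  effects. No gene–gene correlation and no mean–dispersion trend.

All randomness flows from one master seed through named substreams, so
identical config + seed gives byte-identical fixture bundles.

## Numerical choices and degenerate inputs

* Boundary values 1.4/1.9 assign to the lower copy-number class; paralog
  ties at total 3 assign the extra copy to C4A.
* Both paralogs null with a positive total is inconsistent; the caller
  returns (0, total) with a QC flag rather than failing a batch.
* The calibration integral uses a 150-point midpoint rule on [0, 180]
  months and `uniroot` on the log scale; three fixed-point passes suffice
  for the competing antibody streams (scales move < 0.1% on the third
  pass).
* Baseline scales can be computed once (`calibrate_baseline()`) and reused
  across replicates: the baseline hazard is part of the generating model,
  not of the data, and per-replicate recalibration would only add noise
  and cost.
* B8 mode imputation drops missing sites before the mode; an all-missing
  panel is an error, not a 0.

## Known limitations

* The caller resolves total copy numbers only in {2, 3, 4}; values outside
  the observed peaks are flagged, not resolved (no HERV genotyping, no
  C4 > 4 resolution, no Rodgers/Chido isotypes).
* The survival generator draws the clinical endpoints independently of the
  antibody endpoints; in reality T1D follows islet autoimmunity. The Cox
  models fit each endpoint marginally, so this does not affect the
  recovery properties, but joint endpoint trajectories are not realistic.
* Real-data hazard ratios are not reproducible without the
  controlled-access cohort; the acceptance property is parameter recovery
  at the published effect sizes and cohort scale, which validates the
  estimator and encodings, not the original data analysis.
* Expression inference uses per-individual aggregation + OLS, not
  moderated statistics; with ~129 individuals and the configured effects
  this costs little power, but genuinely small effects would suffer.
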