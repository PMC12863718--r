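#' Per-chromosome C4 structure defaults
#'
#' Probabilities of the per-chromosome (C4A, C4B) copy configuration,
#' conditional on whether the chromosome carries the tri-SNP 101 code.
#' Chromosomes carry 1 or 2 C4 modules: structures (1,0), (0,1), (1,1),
#' (2,0), (0,2). Values are maximum-likelihood fits of the diploid marginal
#' columns of the published C4A/C4B-by-dosage cross-tabs
#' ([ref_c4a_dosage_table()], [ref_c4b_dosage_table()]); the joint law is a
#' fitted choice since only marginals are published. 101 chromosomes are
#' dominated by the C4A-deleted, single-C4B structure.
#'
#' @return list with numeric vectors `p101` and `pother` over the five
#'   structures, and integer matrix `structs` of (n_c4a, n_c4b) rows.
#' @export
c4_structure_defaults <- function() {
  structs <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(2L, 0L), c(0L, 2L))
  rownames(structs) <- c("a", "b", "ab", "aa", "bb")
  list(structs = structs,
       p101   = c(a = 0.000, b = 0.922, ab = 0.049, aa = 0.020, bb = 0.009),
       pother = c(a = 0.474, b = 0.000, ab = 0.417, aa = 0.095, bb = 0.014))
}

# pairing preference used to decompose genotype-level tables into
# chromosome-level (HLA haplotype, tri-SNP code) pairs; encodes the known
# strong couplings (101 with DR3, 010 with DR4/DR3).
pairing_affinity <- function(hla, code) {
  key <- paste(hla, code, sep = ":")
  aff <- c("DR3:101" = 3, "DR4:010" = 3, "DR3:010" = 2, "DR8:000" = 2,
           "DR1:001" = 2, "DR13:001" = 2, "DR9:000" = 1, "DR4:000" = 1)
  v <- aff[key]
  ifelse(is.na(v), 0, v)
}

#' Chromosome-level tri-SNP frequencies from a genotype cross-tab
#'
#' Decomposes every cell of an HLA x tri-SNP genotype table into two
#' chromosomes. When both the HLA pair and the tri-SNP pair are heterozygous
#' the phase between them is not identified by the table; the decomposition
#' picks the assignment with the higher linkage-affinity score
#' (deterministic, documented heuristic). Returns, per HLA genotype row, the
#' tri-SNP code distribution of each chromosome slot, plus the pooled
#' chromosome-level (HLA haplotype, code) frequency table.
#'
#' @param table an HLA x tri-SNP [contingency_table] such as
#'   [ref_hla_trisnp_table()].
#' @return list: `rows` (per row label, a list of two named probability
#'   vectors over codes), `haplotypes` (data.frame `hla`, `code`, `count`,
#'   `freq` over all chromosomes).
#' @export
fit_trisnp_conditionals <- function(table) {
  m <- as.matrix(table)
  rows <- list()
  pool <- list()
  for (r in rownames(m)) {
    hla_pair <- parse_genotype_label(r)
    cnt1 <- cnt2 <- numeric(0)
    for (cc in colnames(m)) {
      n <- m[r, cc]
      if (n == 0) next
      tp <- parse_genotype_label(cc)
      s1 <- pairing_affinity(hla_pair[1], tp[1]) + pairing_affinity(hla_pair[2], tp[2])
      s2 <- pairing_affinity(hla_pair[1], tp[2]) + pairing_affinity(hla_pair[2], tp[1])
      assign1 <- if (s2 > s1) c(tp[2], tp[1]) else tp
      cnt1[assign1[1]] <- (if (is.na(cnt1[assign1[1]])) 0 else cnt1[assign1[1]]) + n
      cnt2[assign1[2]] <- (if (is.na(cnt2[assign1[2]])) 0 else cnt2[assign1[2]]) + n
      key1 <- paste(hla_pair[1], assign1[1], sep = ":")
      key2 <- paste(hla_pair[2], assign1[2], sep = ":")
      pool[[key1]] <- (if (is.null(pool[[key1]])) 0 else pool[[key1]]) + n
      pool[[key2]] <- (if (is.null(pool[[key2]])) 0 else pool[[key2]]) + n
    }
    if (hla_pair[1] == hla_pair[2]) {    # homozygous: pool the two slots
      all_codes <- union(names(cnt1), names(cnt2))
      pooled <- setNames(numeric(length(all_codes)), all_codes)
      pooled[names(cnt1)] <- pooled[names(cnt1)] + cnt1
      pooled[names(cnt2)] <- pooled[names(cnt2)] + cnt2
      cnt1 <- cnt2 <- pooled
    }
    rows[[r]] <- list(slot1 = cnt1 / sum(cnt1), slot2 = cnt2 / sum(cnt2))
  }
  keys <- strsplit(names(pool), ":", fixed = TRUE)
  hap <- data.frame(hla = vapply(keys, `[`, "", 1),
                    code = vapply(keys, `[`, "", 2),
                    count = unlist(pool), stringsAsFactors = FALSE)
  hap$freq <- hap$count / sum(hap$count)
  rownames(hap) <- NULL
  list(rows = rows, haplotypes = hap)
}

sim_survival_defaults <- function() {
  panel <- ref_gwas_panel()
  gwas_hr <- function(col) {
    hr <- panel[[paste0("hr_", col)]][panel[[col]]]
    setNames(hr, panel$snp[panel[[col]]])
  }
  hla_t1d <- c("DR3/DR3" = 1.4, "DR3/DR4" = 3.20, "DR4/DR4" = 1.3,
               "DR1/DR4" = 1.9, "DR4/DR13" = 2.0)
  hla_ia  <- c("DR3/DR3" = 1.0, "DR3/DR4" = 1.83, "DR4/DR4" = 1.2,
               "DR1/DR4" = 1.2, "DR4/DR13" = 1.5)
  hla_cd  <- c("DR3/DR3" = 20, "DR3/DR4" = 7, "DR4/DR4" = 5,
               "DR1/DR4" = 3, "DR4/DR13" = 5)
  country_ia <- c(FIN = 1.34, SWE = 1.25)
  stream <- function(target, trisnp, hla, male = 1, fdr = 1, fdr_col = "fdr_t1d",
                     country = NULL, ancestry = NULL, gwas = NULL, gluten = 1,
                     dr3_interaction = 1)
    list(target = target, trisnp_hr = trisnp, hla_hr = hla, male_hr = male,
         fdr_hr = fdr, fdr_col = fdr_col, country_hr = country,
         ancestry_hr = ancestry, gwas_hr = gwas, gluten_hr = gluten,
         dr3_interaction_hr = dr3_interaction)
  list(
    shape = 1.3, admin_censor = 180, dropout_mean = 600,
    streams = list(
      IAA  = stream(313 / 7703, 0.64, hla_ia, male = 1.19, fdr = 2.16,
                    country = country_ia, gwas = gwas_hr("ia")),
      GADA = stream(382 / 7703, 0.87, hla_ia, male = 1.19, fdr = 2.16,
                    country = country_ia, gwas = gwas_hr("ia")),
      OTHER_AB = stream(163 / 7703, 1.00, hla_ia, male = 1.19, fdr = 2.16,
                        country = country_ia, gwas = gwas_hr("ia")),
      T1D  = stream(397 / 7703, 0.54, hla_t1d, fdr = 3.11,
                    country = c(FIN = 1.34), gwas = gwas_hr("t1d")),
      CD   = stream(617 / 7703, 1.32, hla_cd, male = 0.70, fdr = 3.5,
                    fdr_col = "fdr_cd", ancestry = c(AMR = 0.62),
                    gwas = gwas_hr("cd"), gluten = 1.3),
      CDA  = stream(1294 / 6709, 1.23, hla_cd, male = 0.75, fdr = 3.0,
                    fdr_col = "fdr_cd", ancestry = c(AMR = 0.62),
                    gwas = gwas_hr("cda"), gluten = 1.25)))
}

#' Synthetic-cohort configuration
#'
#' All parameters of the generator, with defaults set to the published
#' cohort's stated world: HLA/tri-SNP genotype frequencies from the
#' published cross-tab, C4 structure conditionals fitted to the published
#' copy-number tables, marginal covariate distributions from the cohort
#' descriptives, per-endpoint tri-SNP hazard ratios and event fractions from
#' the published models, a coverage model with per-copy unique-read signal
#' 0.3, and a negative-binomial expression model with opposite-sign C4A/C4B
#' dosage effects. Any sub-list can be partially overridden; supplied
#' entries are merged over the defaults.
#'
#' @param n_subjects cohort size (published: 7759 typed children).
#' @param hw_mode `"rows"` (default: HLA genotype drawn from the published
#'   row distribution, tri-SNP codes from row-conditional chromosome
#'   frequencies -- matches the HLA-ascertained cohort) or `"hw"`
#'   (Hardy-Weinberg i.i.d. haplotype draws from the pooled chromosome
#'   frequency table).
#' @param table1 HLA x tri-SNP genotype [contingency_table] to fit
#'   frequencies from.
#' @param c4,b8,covariates,surv,coverage,expression partial override lists;
#'   see the method vignette for every field, unit and default.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 7759L, hw_mode = c("rows", "hw"),
                       table1 = ref_hla_trisnp_table(),
                       c4 = list(), b8 = list(), covariates = list(),
                       surv = list(), coverage = list(), expression = list()) {
  hw_mode <- match.arg(hw_mode)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    hw_mode = hw_mode,
    table1 = table1,
    c4 = modifyList(c4_structure_defaults(), c4),
    b8 = modifyList(list(p_given_101 = 0.80, p_given_other = 0.05,
                         panel_size = 20L, p_alt_given_b8 = 0.97,
                         p_alt_given_not = 0.03), b8),
    covariates = modifyList(list(
      sex_female = 3778 / 7703,
      country = c(US = 3182, SWE = 2309, FIN = 1696, GER = 516) / 7703,
      ancestry = c(EUR = 6953, AMR = 707, AFR = 82, SAS = 14, EAS = 3) / 7759,
      fdr_t1d = 857 / 7703, fdr_cd = 361 / 7703,
      gwas_maf = 0.2), covariates),
    surv = modifyList(sim_survival_defaults(), surv),
    coverage = modifyList(list(
      flank_depth_mean = 30, flank_depth_sd = 3, noise_cv = 0.05,
      unique_rate = 0.3, uniq_background = 0.05, uniq_outside = 0.98,
      herv_presence = 0.6, n_wgs = 188L,
      window_start = 28510000L, window_end = 33482000L), coverage),
    expression = modifyList(list(
      n_individuals = 129L, n_genes = 2000L, samples_per_ind_lambda = 3.17,
      lib_size_range = c(2e7, 4e7), dispersion = 0.3,
      baseline_log_cpm_mean = log(50), baseline_log_cpm_sd = 1.2,
      c4a_effect = -1, c4b_effect = 0.5, c4_baseline_cpm = 200,
      n_batches = 3L, batch_sd = 0.15, age_effect_sd = 0.3,
      age_affected_frac = 0.1, p_lt1y = 0.25), expression))
  probs <- rowSums(as.matrix(table1)) / sum(table1)
  if (abs(sum(probs) - 1) > 1e-8)
    tc4_stop("triC4_config", "HLA row frequencies do not sum to 1")
  for (p in list(cfg$c4$p101, cfg$c4$pother))
    if (abs(sum(p) - 1) > 1e-6)
      tc4_stop("triC4_config", "C4 structure probabilities must sum to 1")
  cfg$hla_row_probs <- probs
  cfg$trisnp_cond <- fit_trisnp_conditionals(table1)
  class(cfg) <- "sim_config"
  cfg
}

#' Draw genotypes for a synthetic cohort
#'
#' Draws, per subject, an HLA genotype and two per-chromosome haplotypes
#' (tri-SNP code, C4 structure, B8 flag, B8 tag-panel alleles), either
#' row-conditionally (default; reproduces the ascertained genotype
#' distribution) or as i.i.d. haplotype draws under Hardy-Weinberg.
#' Deterministic under `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @return data.frame, one row per subject, with per-chromosome fields
#'   (`hapA_*`, `hapB_*`), the derived `trisnp` genotype string,
#'   `trisnp_dosage` (count of 101 alleles), true diploid copy numbers
#'   `gcn_a`, `gcn_b`, `total_gcn` and `b8_dosage`. B8 panel haplotype
#'   alleles are attached as attribute `b8_panel` (two 0/1 matrices).
#' @export
sample_genotypes <- function(config, seed) {
  with_seed(substream_seed(seed, "genotypes"), {
    n <- config$n_subjects
    if (config$hw_mode == "rows") {
      rows <- sample(names(config$hla_row_probs), n, replace = TRUE,
                     prob = config$hla_row_probs)
      hla_pair <- t(vapply(rows, parse_genotype_label, character(2)))
      codeA <- codeB <- character(n)
      for (r in unique(rows)) {
        idx <- which(rows == r)
        cond <- config$trisnp_cond$rows[[r]]
        codeA[idx] <- sample(names(cond$slot1), length(idx), replace = TRUE,
                             prob = cond$slot1)
        codeB[idx] <- sample(names(cond$slot2), length(idx), replace = TRUE,
                             prob = cond$slot2)
      }
      hla <- rows
    } else {
      hap <- config$trisnp_cond$haplotypes
      iA <- sample(nrow(hap), n, replace = TRUE, prob = hap$freq)
      iB <- sample(nrow(hap), n, replace = TRUE, prob = hap$freq)
      hla_pair <- cbind(hap$hla[iA], hap$hla[iB])
      codeA <- hap$code[iA]; codeB <- hap$code[iB]
      ord <- c("DR1", "DR3", "DR4", "DR8", "DR9", "DR13")
      hla <- apply(hla_pair, 1, function(p)
        paste(p[order(match(p, ord))], collapse = "/"))
    }
    draw_struct <- function(is101) {
      k <- integer(length(is101))
      p1 <- config$c4$p101; p0 <- config$c4$pother
      k[is101] <- sample.int(5L, sum(is101), replace = TRUE, prob = p1)
      k[!is101] <- sample.int(5L, sum(!is101), replace = TRUE, prob = p0)
      config$c4$structs[k, , drop = FALSE]
    }
    a101 <- codeA == "101"; b101 <- codeB == "101"
    sA <- draw_struct(a101); sB <- draw_struct(b101)
    b8A <- rbinom(n, 1, ifelse(a101, config$b8$p_given_101, config$b8$p_given_other))
    b8B <- rbinom(n, 1, ifelse(b101, config$b8$p_given_101, config$b8$p_given_other))
    ps <- config$b8$panel_size
    panelA <- matrix(rbinom(n * ps, 1,
                            rep(ifelse(b8A == 1, config$b8$p_alt_given_b8,
                                       config$b8$p_alt_given_not), ps)), n, ps)
    panelB <- matrix(rbinom(n * ps, 1,
                            rep(ifelse(b8B == 1, config$b8$p_alt_given_b8,
                                       config$b8$p_alt_given_not), ps)), n, ps)
    geno <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      hla = hla,
      hapA_hla = hla_pair[, 1], hapB_hla = hla_pair[, 2],
      hapA_trisnp = codeA, hapB_trisnp = codeB,
      trisnp = vapply(seq_len(n), function(i)
        paste(sort(c(codeA[i], codeB[i])), collapse = "/"), character(1)),
      trisnp_dosage = as.integer(a101) + as.integer(b101),
      hapA_c4a = sA[, 1], hapA_c4b = sA[, 2],
      hapB_c4a = sB[, 1], hapB_c4b = sB[, 2],
      gcn_a = sA[, 1] + sB[, 1], gcn_b = sA[, 2] + sB[, 2],
      hapA_b8 = b8A, hapB_b8 = b8B,
      b8_dosage = b8A + b8B,
      stringsAsFactors = FALSE)
    geno$total_gcn <- geno$gcn_a + geno$gcn_b
    attr(geno, "b8_panel") <- list(hapA = panelA, hapB = panelB)
    rownames(geno) <- NULL
    geno
  })
}

#' Draw demographic and genetic covariates
#'
#' Sex, country, genetic ancestry, disease-specific first-degree-relative
#' flags, a standardized gluten-intake score and the GWAS panel dosages
#' (binomial with a common minor-allele frequency), all as independent
#' categoricals/numerics with the cohort's marginal frequencies.
#'
#' @param geno genotype data.frame from [sample_genotypes()].
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @return `geno` with covariate columns appended (GWAS dosages as
#'   `gwas_<rsid>`... no prefix: the rsid itself).
#' @export
simulate_covariates <- function(geno, config, seed) {
  with_seed(substream_seed(seed, "covariates"), {
    n <- nrow(geno)
    cv <- config$covariates
    geno$sex <- ifelse(runif(n) < cv$sex_female, "female", "male")
    geno$country <- sample(names(cv$country), n, TRUE, cv$country)
    geno$ancestry <- sample(names(cv$ancestry), n, TRUE, cv$ancestry)
    geno$fdr_t1d <- rbinom(n, 1, cv$fdr_t1d)
    geno$fdr_cd <- rbinom(n, 1, cv$fdr_cd)
    geno$gluten <- rnorm(n)
    for (s in ref_gwas_panel()$snp)
      geno[[s]] <- rbinom(n, 2, cv$gwas_maf)
    geno
  })
}

# linear predictor (log hazard scale) of one stream for every subject
stream_lp <- function(cohort, st) {
  lp <- log(st$trisnp_hr) * cohort$trisnp_dosage
  hla_hr <- st$hla_hr[cohort$hla]
  hla_hr[is.na(hla_hr)] <- 1
  lp <- lp + log(hla_hr)
  lp <- lp + ifelse(cohort$sex == "male", log(st$male_hr), 0)
  lp <- lp + log(st$fdr_hr) * cohort[[st$fdr_col]]
  for (cn in names(st$country_hr))
    lp <- lp + ifelse(cohort$country == cn, log(st$country_hr[[cn]]), 0)
  for (an in names(st$ancestry_hr))
    lp <- lp + ifelse(cohort$ancestry == an, log(st$ancestry_hr[[an]]), 0)
  for (sn in names(st$gwas_hr))
    if (sn %in% names(cohort)) lp <- lp + log(st$gwas_hr[[sn]]) * cohort[[sn]]
  if (!is.null(st$gluten_hr) && st$gluten_hr != 1 && "gluten" %in% names(cohort))
    lp <- lp + log(st$gluten_hr) * cohort$gluten
  if (st$dr3_interaction_hr != 1)
    lp <- lp + log(st$dr3_interaction_hr) * cohort$trisnp_dosage *
      (cohort$hla == "DR3/DR3")
  unname(lp)
}

# calibrate the Weibull baseline scale of each stream so that the expected
# observed-event fraction matches its target, accounting for administrative
# censoring, exponential dropout and (for competing antibody streams) the
# survival of the competitors. Midpoint-rule integration over [0, admin];
# competing streams are resolved by 3 fixed-point passes.
calibrate_scales <- function(lps, targets, shape, admin, dropout_mean,
                             competing = NULL) {
  k <- shape
  nt <- 150L
  tgrid <- (seq_len(nt) - 0.5) * admin / nt
  dt <- admin / nt
  tk <- tgrid^k
  base_row <- k * tgrid^(k - 1) * exp(-tgrid / dropout_mean) * dt
  elps <- lapply(lps, exp)
  scales <- rep(admin * 4, length(lps))
  names(scales) <- names(lps)
  # expected observed-event fraction of stream j at scale s, with the
  # competitor survival matrix fixed (computed once per uniroot call chain)
  for (pass in 1:3) {
    for (j in seq_along(lps)) {
      e <- elps[[j]]
      s_other <- 1
      if (!is.null(competing)) {
        for (jj in competing[[j]])
          s_other <- s_other * exp(-(elps[[jj]] %o% tk) / scales[jj]^k)
      }
      f <- function(ls) {
        sk <- exp(ls)^k
        surv <- exp(-(e %o% tk) / sk)
        if (!identical(s_other, 1)) surv <- surv * s_other
        mean(e * (surv %*% (base_row / sk))) - targets[j]
      }
      scales[j] <- exp(uniroot(f, lower = log(20), upper = log(5e5),
                               tol = 1e-4)$root)
    }
    if (is.null(competing)) break
  }
  scales
}

#' Calibrate baseline Weibull scales for the outcome streams
#'
#' Solves, per stream, for the baseline Weibull scale (months) at which the
#' expected observed-event fraction over the realized cohort covariates
#' equals the stream's configured target, under administrative censoring,
#' exponential dropout and antibody-stream competition. The result can be
#' passed to [simulate_outcomes()] to skip per-replicate recalibration
#' (the baseline hazard is part of the generating model, not of the data).
#'
#' @param cohort covariate-complete cohort data.frame.
#' @param config a [sim_config()].
#' @return named numeric vector of scales, one per stream.
#' @export
calibrate_baseline <- function(cohort, config) {
  sv <- config$surv
  st <- sv$streams
  lps <- lapply(st, function(s) stream_lp(cohort, s))
  targets <- vapply(st, function(s) s$target, numeric(1))
  ab <- c("IAA", "GADA", "OTHER_AB")
  competing <- list(IAA = c("GADA", "OTHER_AB"), GADA = c("IAA", "OTHER_AB"),
                    OTHER_AB = c("IAA", "GADA"))
  sc_ab <- calibrate_scales(lps[ab], targets[ab], sv$shape, sv$admin_censor,
                            sv$dropout_mean, competing = competing)
  others <- setdiff(names(st), ab)
  sc_other <- calibrate_scales(lps[others], targets[others], sv$shape,
                               sv$admin_censor, sv$dropout_mean)
  c(sc_ab, sc_other)
}

#' Simulate endpoint times and censoring
#'
#' Weibull proportional-hazards latent times per stream (linear predictor =
#' sum of covariate x log hazard ratio), administrative censoring at 180
#' months plus exponential dropout. The three islet-autoantibody streams
#' (IAA, GADA, other) compete: the earliest determines the first-appearing
#' antibody and the islet-autoimmunity event; T1D, CD and CDA are separate
#' streams. Baseline scales are calibrated so each stream's expected
#' observed-event fraction matches its configured target.
#'
#' @param cohort data.frame from [simulate_covariates()].
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @param scales optional pre-computed baseline scales from
#'   [calibrate_baseline()]; calibrated on the fly when NULL.
#' @return `cohort` with outcome columns: `ab_type`, `ab_time`, `ia_event`,
#'   `ia_time`, and `<ep>_event`/`<ep>_time` for t1d, cd, cda.
#' @export
simulate_outcomes <- function(cohort, config, seed, scales = NULL) {
  if (is.null(scales)) scales <- calibrate_baseline(cohort, config)
  with_seed(substream_seed(seed, "outcomes"), {
    sv <- config$surv
    n <- nrow(cohort)
    st <- sv$streams
    lps <- lapply(st, function(s) stream_lp(cohort, s))
    ab <- c("IAA", "GADA", "OTHER_AB")
    draw <- function(nm) {
      lam <- scales[[nm]] * exp(-lps[[nm]] / sv$shape)
      lam * (-log(runif(n)))^(1 / sv$shape)
    }
    times <- lapply(setNames(names(st), names(st)), draw)
    cens <- pmin(sv$admin_censor, rexp(n, rate = 1 / sv$dropout_mean))
    t_ab <- pmin(times$IAA, times$GADA, times$OTHER_AB)
    which_ab <- ab[max.col(-cbind(times$IAA, times$GADA, times$OTHER_AB))]
    has_ab <- t_ab < cens
    cohort$ab_type <- ifelse(has_ab, which_ab, "none")
    cohort$ab_time <- ifelse(has_ab, t_ab, NA_real_)
    cohort$ia_event <- as.integer(has_ab)
    cohort$ia_time <- pmin(t_ab, cens)
    for (nm in c("T1D", "CD", "CDA")) {
      ev <- times[[nm]] < cens
      cohort[[paste0(tolower(nm), "_event")]] <- as.integer(ev)
      cohort[[paste0(tolower(nm), "_time")]] <- pmin(times[[nm]], cens)
    }
    cohort
  })
}

#' Simulate a complete cohort
#'
#' Genotypes, covariates and outcomes in one call; the three substreams are
#' derived from the single master seed.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @param scales optional pre-computed baseline scales (see
#'   [calibrate_baseline()]).
#' @return cohort data.frame.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L, scales = NULL) {
  geno <- sample_genotypes(config, seed)
  cohort <- simulate_covariates(geno, config, seed)
  b8p <- attr(geno, "b8_panel")
  cohort <- simulate_outcomes(cohort, config, seed, scales = scales)
  attr(cohort, "b8_panel") <- b8p
  cohort
}

#' Simulate windowed WGS coverage profiles
#'
#' Per-sample mean depth over the 1 kb MHC windows, all-read and unique-read
#' (MAPQ >= 30) classes, under the signal model the caller assumes: all-read
#' C4-region depth proportional to total copy number over the two reference
#' loci (diploid-normalized values 1, 1.5, 2 for totals 2, 3, 4), unique
#' discriminating-region depth 0.3 per paralog copy, flanks diploid, and
#' multiplicative log-normal window noise at the configured coefficient of
#' variation (mean-corrected, so region means are unbiased).
#'
#' @param samples data.frame with `subject_id`, `gcn_a`, `gcn_b` (e.g. rows
#'   of a simulated cohort).
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @param region_config a [c4_region_config()] (geometry of the signal).
#' @return a `coverage_set`: `sample_ids`, `windows`, `depth_all`,
#'   `depth_uniq` matrices (samples x windows).
#' @export
simulate_coverage <- function(samples, config, seed,
                              region_config = c4_region_config()) {
  with_seed(substream_seed(seed, "coverage"), {
    cv <- config$coverage
    windows <- mhc_windows(cv$window_start, cv$window_end)
    W <- nrow(windows)
    n <- nrow(samples)
    c4_idx <- windows_in(windows, region_config$c4_intervals)
    herv_idx <- windows_in(windows, list(region_config$herv))
    a_idx <- windows_in(windows, list(region_config$c4a_unique))
    b_idx <- windows_in(windows, list(region_config$c4b_unique))
    g <- samples$gcn_a + samples$gcn_b
    f_all <- matrix(1, n, W)
    f_all[, c4_idx] <- g / 4
    f_all[, herv_idx] <- (g / 4) * cv$herv_presence
    f_uniq <- matrix(cv$uniq_outside, n, W)
    f_uniq[, c4_idx] <- (g / 4) * cv$uniq_background
    f_uniq[, a_idx] <- cv$unique_rate * samples$gcn_a / 2
    f_uniq[, b_idx] <- cv$unique_rate * samples$gcn_b / 2
    D <- pmax(rnorm(n, cv$flank_depth_mean, cv$flank_depth_sd), 5)
    sdlog <- sqrt(log(1 + cv$noise_cv^2))
    noise <- function() matrix(exp(rnorm(n * W, -sdlog^2 / 2, sdlog)), n, W)
    depth_all <- D * f_all * noise()
    depth_uniq <- D * f_uniq * noise()
    structure(list(sample_ids = samples$subject_id, windows = windows,
                   depth_all = depth_all, depth_uniq = depth_uniq),
              class = "coverage_set")
  })
}

#' Simulate an RNA count matrix with tri-SNP dosage effects
#'
#' Negative-binomial counts for `n_genes` genes over multiple blood samples
#' per individual, with designated `C4A_like` (negative) and `C4B_like`
#' (positive) log2-per-allele dosage effects, batch/age/sex nuisance effects
#' and log-normal baseline abundances. Individuals default to a DR3/DR3-like
#' dosage distribution; pass `dosage` to reuse cohort genotypes.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @param dosage optional named vector of per-individual 101 dosages.
#' @return an [expression_set()].
#' @export
simulate_expression <- function(config, seed, dosage = NULL) {
  with_seed(substream_seed(seed, "expression"), {
    ex <- config$expression
    if (is.null(dosage)) {
      cond <- config$trisnp_cond$rows[["DR3/DR3"]]$slot1
      p101 <- if ("101" %in% names(cond)) cond[["101"]] else 0.84
      nind <- ex$n_individuals
      dosage <- setNames(rbinom(nind, 2, p101), sprintf("I%04d", seq_len(nind)))
    }
    nind <- length(dosage)
    inds <- names(dosage)
    nsamp_per <- 1L + rpois(nind, ex$samples_per_ind_lambda)
    sid <- unlist(lapply(seq_len(nind), function(i)
      sprintf("%s_s%d", inds[i], seq_len(nsamp_per[i]))))
    ind_of <- rep(inds, nsamp_per)
    ns <- length(sid)
    samples <- data.frame(
      sample_id = sid, individual_id = ind_of,
      batch = sample(sprintf("b%d", seq_len(ex$n_batches)), ns, TRUE),
      age_cat = ifelse(runif(ns) < ex$p_lt1y, "lt1y", "ge1y"),
      sex = rep(ifelse(runif(nind) < 0.5, "female", "male"), nsamp_per),
      stringsAsFactors = FALSE)
    G <- ex$n_genes
    genes <- sprintf("gene%04d", seq_len(G))
    base_cpm <- exp(rnorm(G, ex$baseline_log_cpm_mean, ex$baseline_log_cpm_sd))
    beta <- numeric(G)
    genes[1] <- "C4A_like"; base_cpm[1] <- ex$c4_baseline_cpm; beta[1] <- ex$c4a_effect
    genes[2] <- "C4B_like"; base_cpm[2] <- ex$c4_baseline_cpm; beta[2] <- ex$c4b_effect
    batch_eff <- matrix(rnorm(G * ex$n_batches, 0, ex$batch_sd), G, ex$n_batches,
                        dimnames = list(NULL, sprintf("b%d", seq_len(ex$n_batches))))
    age_eff <- ifelse(runif(G) < ex$age_affected_frac,
                      rnorm(G, 0, ex$age_effect_sd), 0)
    lib <- round(runif(ns, ex$lib_size_range[1], ex$lib_size_range[2]))
    dose_s <- dosage[ind_of]
    log2mu <- outer(log2(base_cpm), log2(lib / 1e6), "+") +
      beta %o% dose_s +
      batch_eff[, samples$batch] +
      age_eff %o% as.numeric(samples$age_cat == "lt1y")
    mu <- 2^log2mu
    counts <- matrix(rnbinom(G * ns, size = 1 / ex$dispersion, mu = mu), G, ns,
                     dimnames = list(genes, sid))
    expression_set(counts, samples, dosage)
  })
}
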