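#' Endpoints supported by the time-to-event models
#' @export
tc4_endpoints <- function() c("T1D", "IA", "IAA_first", "GADA_first", "CD", "CDA")

#' Cox model specification
#'
#' Covariate encoding and filtering rules for one endpoint/scope pair. Age in
#' months is the time axis. Tri-SNP 101, B8 and GWAS dosages enter as numeric
#' additive covariates (hazard ratios are per additional allele); HLA
#' genotype, sex, country and genetic ancestry are categorical with baselines
#' DR4/DR8, female, US and EUR; first-degree-relative status is 0/1. The
#' GWAS covariates default to the endpoint-appropriate set of the published
#' panel ([ref_gwas_panel()]); first-antibody endpoints reuse the IA set, and
#' a gluten-intake covariate is added for CD/CDA.
#'
#' @param endpoint one of [tc4_endpoints()].
#' @param scope `"all"` or `"DR3_homozygous"` (restricts to DR3/DR3 subjects
#'   and drops the HLA covariate).
#' @param exposure name of the numeric exposure column, default
#'   `"trisnp_dosage"`; set `"b8_dosage"` for the extended-haplotype
#'   comparison models.
#' @param gwas_snps character vector of GWAS covariate columns; NULL =
#'   endpoint default from the panel.
#' @param min_category_size categorical levels smaller than this are removed
#'   before fitting (published rule: 20).
#' @param extra_covariates additional numeric covariate columns (e.g.
#'   `"gluten"`; added automatically for CD/CDA).
#' @return list of class `cox_model_spec`.
#' @export
cox_model_spec <- function(endpoint, scope = c("all", "DR3_homozygous"),
                           exposure = "trisnp_dosage", gwas_snps = NULL,
                           min_category_size = 20L, extra_covariates = NULL) {
  endpoint <- match.arg(endpoint, tc4_endpoints())
  scope <- match.arg(scope)
  if (is.null(gwas_snps)) {
    panel <- ref_gwas_panel()
    col <- switch(endpoint, T1D = "t1d", CD = "cd", CDA = "cda", "ia")
    gwas_snps <- panel$snp[panel[[col]]]
  }
  if (endpoint %in% c("CD", "CDA") && !("gluten" %in% extra_covariates))
    extra_covariates <- c(extra_covariates, "gluten")
  categorical <- c(hla = "DR4/DR8", sex = "female", country = "US",
                   ancestry = "EUR")
  if (scope == "DR3_homozygous") categorical <- categorical[names(categorical) != "hla"]
  fdr_col <- if (endpoint %in% c("CD", "CDA")) "fdr_cd" else "fdr_t1d"
  structure(list(endpoint = endpoint, scope = scope, exposure = exposure,
                 categorical = categorical, fdr_col = fdr_col,
                 gwas_snps = gwas_snps, extra_covariates = extra_covariates,
                 min_category_size = as.integer(min_category_size)),
            class = "cox_model_spec")
}

#' Derive (time, event) for an endpoint
#'
#' Clinical endpoints (T1D, CD) use age at diagnosis as the event time and
#' age at the latest clinic visit as the right-censor time; antibody
#' endpoints (IA, CDA) censor at the last negative serum sample. For the
#' first-appearing-autoantibody endpoints, subjects whose first islet
#' autoantibody is a different one are right-censored at its appearance
#' time. Subjects with a missing time are dropped and recorded in the
#' `"dropped"` attribute.
#'
#' @param records cohort data.frame (see [simulate_cohort()] for the schema:
#'   `t1d_time`/`t1d_event`, `cd_*`, `cda_*`, `ia_*`, plus `ab_type` and
#'   `ab_time` for the antibody-identity endpoints).
#' @param endpoint one of [tc4_endpoints()].
#' @return data.frame `subject_id`, `time`, `event` with attribute
#'   `dropped` (character vector of subject ids removed for missing data).
#' @export
prepare_endpoint <- function(records, endpoint) {
  endpoint <- match.arg(endpoint, tc4_endpoints())
  if (endpoint %in% c("IAA_first", "GADA_first")) {
    want <- if (endpoint == "IAA_first") "IAA" else "GADA"
    has_ab <- !is.na(records$ab_type) & records$ab_type != "none"
    time <- ifelse(has_ab, records$ab_time, records$ia_time)
    event <- as.integer(has_ab & records$ab_type == want)
  } else {
    cols <- switch(endpoint, T1D = c("t1d_time", "t1d_event"),
                   CD = c("cd_time", "cd_event"),
                   IA = c("ia_time", "ia_event"),
                   CDA = c("cda_time", "cda_event"))
    time <- records[[cols[1]]]
    event <- as.integer(records[[cols[2]]])
  }
  keep <- !is.na(time) & time > 0 & !is.na(event)
  out <- data.frame(subject_id = records$subject_id[keep],
                    time = time[keep], event = event[keep],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- records$subject_id[!keep]
  out
}

# covariate columns a spec touches
spec_covariates <- function(spec) {
  c(names(spec$categorical), spec$fdr_col, spec$exposure,
    spec$gwas_snps, spec$extra_covariates)
}

#' Filter a model frame to fittable categories
#'
#' Applies, iterated to a fixed point (making the result order-independent):
#' complete-case removal on the model covariates and time/event; removal of
#' subjects in any categorical level with fewer than `min_category_size`
#' members; removal of levels with zero events or zero non-events (the
#' partial likelihood cannot separate such levels from the baseline).
#'
#' @param frame data.frame containing `time`, `event` and the spec's
#'   covariate columns.
#' @param spec a [cox_model_spec()].
#' @return the filtered frame; attribute `drop_log` records per-pass reasons
#'   and counts.
#' @export
filter_model_frame <- function(frame, spec) {
  log <- list()
  covs <- intersect(spec_covariates(spec), names(frame))
  repeat {
    n0 <- nrow(frame)
    cc <- complete.cases(frame[, c("time", "event", covs), drop = FALSE])
    if (any(!cc)) log <- c(log, list(c(reason = "missing_covariates", n = sum(!cc))))
    frame <- frame[cc, , drop = FALSE]
    for (v in names(spec$categorical)) {
      if (!v %in% names(frame)) next
      tab <- table(frame[[v]])
      small <- names(tab)[tab < spec$min_category_size]
      ev <- tapply(frame$event, frame[[v]], sum)
      bad_ev <- names(ev)[ev == 0 | ev == tab[names(ev)]]
      drop_lv <- union(small, bad_ev)
      if (length(drop_lv)) {
        hit <- frame[[v]] %in% drop_lv
        log <- c(log, list(c(reason = paste0(v, ":", paste(drop_lv, collapse = ",")),
                             n = sum(hit))))
        frame <- frame[!hit, , drop = FALSE]
      }
    }
    if (nrow(frame) == n0) break
    if (nrow(frame) == 0L)
      tc4_stop("triC4_empty_frame", "no subjects left after category filtering")
  }
  if (nrow(frame) == 0L)
    tc4_stop("triC4_empty_frame", "no subjects left after category filtering")
  attr(frame, "drop_log") <- log
  frame
}

#' Fit a Cox proportional-hazards model
#'
#' Builds the design from a filtered frame (categorical covariates releveled
#' to the spec baselines, numeric covariates as-is) and maximizes the Cox
#' partial likelihood with Efron tie handling via [survival::coxph()]. Wald
#' 95% confidence intervals and p-values per covariate.
#'
#' @param frame filtered data.frame with `time`, `event` and covariates (as
#'   from [filter_model_frame()]).
#' @param spec a [cox_model_spec()].
#' @return data.frame of class `cox_fit`: `covariate`, `log_hr`, `hr`,
#'   `ci95_low`, `ci95_high`, `p_value`; attributes `n_used`, `n_events`,
#'   `converged`, `endpoint`, `scope`.
#' @export
fit_cox <- function(frame, spec) {
  if (sum(frame$event) < 1L)
    tc4_stop("triC4_no_events", "at least one event is required")
  dat <- frame
  terms <- character()
  for (v in names(spec$categorical)) {
    if (!v %in% names(dat)) next
    f <- factor(dat[[v]])
    if (nlevels(f) < 2L) next           # constant in scope (e.g. hla in DR3/DR3)
    if (spec$categorical[[v]] %in% levels(f))
      f <- stats::relevel(f, ref = spec$categorical[[v]])
    dat[[v]] <- f
    terms <- c(terms, v)
  }
  num <- intersect(c(spec$fdr_col, spec$exposure, spec$gwas_snps,
                     spec$extra_covariates), names(dat))
  num <- num[vapply(num, function(v) var(dat[[v]]) > 0, logical(1))]
  terms <- c(terms, num)
  if (!length(terms)) tc4_stop("triC4_config", "no usable covariates")
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(sprintf("`%s`", terms), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (any(!is.finite(b)) || any(!is.finite(se)))
    tc4_stop("triC4_convergence", "Cox fit failed to produce finite estimates")
  z <- qnorm(0.975)
  out <- data.frame(covariate = names(b), log_hr = unname(b),
                    hr = exp(unname(b)),
                    ci95_low = exp(unname(b) - z * se),
                    ci95_high = exp(unname(b) + z * se),
                    se = unname(se),
                    p_value = 2 * stats::pnorm(-abs(unname(b) / se)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cox_fit", class(out))
  attr(out, "n_used") <- nrow(dat)
  attr(out, "n_events") <- sum(dat$event)
  attr(out, "converged") <- converged
  attr(out, "endpoint") <- spec$endpoint
  attr(out, "scope") <- spec$scope
  out
}

#' Build, filter and fit one endpoint/scope model
#'
#' Convenience composition: derive (time, event), restrict the scope, filter
#' categories, fit.
#'
#' @param cohort cohort data.frame.
#' @param spec a [cox_model_spec()].
#' @return a `cox_fit` (see [fit_cox()]).
#' @export
fit_endpoint_model <- function(cohort, spec) {
  te <- prepare_endpoint(cohort, spec$endpoint)
  frame <- merge(cohort, te, by = "subject_id")
  if (spec$scope == "DR3_homozygous")
    frame <- frame[frame$hla == "DR3/DR3", , drop = FALSE]
  frame <- filter_model_frame(frame, spec)
  fit_cox(frame, spec)
}

#' Fit the full grid of published models
#'
#' Six endpoints x two scopes (full cohort and DR3/DR3-restricted), each with
#' the endpoint-appropriate GWAS covariate set. Endpoints that cannot be fit
#' in a scope (e.g. zero events) are skipped with a recorded reason.
#'
#' @param cohort cohort data.frame.
#' @param exposure exposure column, default `"trisnp_dosage"` (use
#'   `"b8_dosage"` for the extended-haplotype comparison).
#' @return list with `fits` (named list of `cox_fit`), `skipped` (named
#'   character of reasons), and `summary` (long data.frame of the exposure
#'   row of every fit: endpoint, scope, hr, ci, p, n, n_events).
#' @export
run_paper_models <- function(cohort, exposure = "trisnp_dosage") {
  fits <- list(); skipped <- character(); rows <- list()
  for (ep in tc4_endpoints()) for (sc in c("all", "DR3_homozygous")) {
    key <- paste(ep, sc, sep = ".")
    spec <- cox_model_spec(ep, sc, exposure = exposure)
    res <- tryCatch(fit_endpoint_model(cohort, spec),
                    triC4_error = function(e) conditionMessage(e))
    if (is.character(res)) { skipped[key] <- res; next }
    fits[[key]] <- res
    i <- match(exposure, res$covariate)
    rows[[key]] <- data.frame(endpoint = ep, scope = sc,
                              log_hr = res$log_hr[i], hr = res$hr[i],
                              ci95_low = res$ci95_low[i],
                              ci95_high = res$ci95_high[i],
                              p_value = res$p_value[i],
                              n = attr(res, "n_used"),
                              n_events = attr(res, "n_events"),
                              stringsAsFactors = FALSE)
  }
  list(fits = fits, skipped = skipped,
       summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
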