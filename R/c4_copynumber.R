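#' 1 kb windows over the MHC
#'
#' Non-overlapping 1 kb windows (BED convention: 0-based, half-open) spanning
#' the MHC region used for read-depth extraction.
#'
#' @param start,end region bounds (defaults chr6:28510000-33482000, hg38).
#' @param width window width in bp.
#' @param chrom chromosome name.
#' @return data.frame `chrom`, `start`, `end`; all windows of `width` except
#'   possibly the last.
#' @export
mhc_windows <- function(start = 28510000L, end = 33482000L, width = 1000L,
                        chrom = "chr6") {
  s <- seq.int(start, end - 1L, by = width)
  e <- pmin(s + width, end)
  data.frame(chrom = chrom, start = s, end = e)
}

#' C4 region configuration
#'
#' Genomic intervals and thresholds driving the C4 copy-number caller. The
#' gene/discriminating-region/HERV coordinates are parameters with hg38-based
#' approximate defaults aligned to the 1 kb window grid; the thresholds are
#' the published calling rule: total-copy-number peak cut-offs at 1.4 and
#' 1.9 on diploid-normalized all-read coverage, paralog-null cut-off 0.04 on
#' unique-read coverage, and an A:B coverage-ratio cut-off of 2.5 for the
#' 3+1 split of 4-copy samples.
#'
#' @param c4_intervals list of c(start, end) intervals covering the C4A and
#'   C4B gene bodies (both paralogous loci of the reference).
#' @param herv interval of the intronic HERV insertion, excluded from the
#'   total-C4 coverage average.
#' @param c4a_unique,c4b_unique the ~3 kb paralog-discriminating regions.
#' @param flank_size flanking span (bp) on each side of the C4 locus used for
#'   per-sample diploid normalization.
#' @param null_cutoff,gcn2_upper,gcn3_upper,ratio_cutoff,low_total_flag
#'   calling thresholds; see Details above.
#' @return list of class `c4_region_config`.
#' @export
c4_region_config <- function(c4_intervals = list(c(31982000L, 32003000L),
                                                 c(32015000L, 32035000L)),
                             herv = c(31985000L, 31992000L),
                             c4a_unique = c(31996000L, 31999000L),
                             c4b_unique = c(32028000L, 32031000L),
                             flank_size = 25000L,
                             null_cutoff = 0.04,
                             gcn2_upper = 1.4,
                             gcn3_upper = 1.9,
                             ratio_cutoff = 2.5,
                             low_total_flag = 0.7) {
  if (!(null_cutoff < low_total_flag && low_total_flag < gcn2_upper &&
        gcn2_upper < gcn3_upper))
    tc4_stop("triC4_config", "thresholds must be strictly increasing")
  lo <- min(vapply(c4_intervals, `[`, numeric(1), 1))
  hi <- max(vapply(c4_intervals, `[`, numeric(1), 2))
  structure(list(c4_intervals = c4_intervals, herv = herv,
                 c4a_unique = c4a_unique, c4b_unique = c4b_unique,
                 flanks = list(c(lo - flank_size, lo), c(hi, hi + flank_size)),
                 null_cutoff = null_cutoff, gcn2_upper = gcn2_upper,
                 gcn3_upper = gcn3_upper, ratio_cutoff = ratio_cutoff,
                 low_total_flag = low_total_flag),
            class = "c4_region_config")
}

# indices of windows whose midpoint falls in any of the given intervals
windows_in <- function(windows, intervals, exclude = NULL) {
  mid <- (windows$start + windows$end) / 2
  hit <- Reduce(`|`, lapply(intervals, function(iv) mid >= iv[1] & mid < iv[2]))
  if (!is.null(exclude))
    hit <- hit & !(mid >= exclude[1] & mid < exclude[2])
  which(hit)
}

#' Per-window mean depth from summed base coverage
#'
#' Converts `samtools bedcov`-style output (summed per-base coverage per
#' window) to mean depth: sum / window length. Records must match the window
#' set row-for-row (same order, same coordinates).
#'
#' @param bedcov data.frame with `chrom`, `start`, `end`, `sum`.
#' @param windows window set from [mhc_windows()].
#' @return numeric vector of per-window mean depths.
#' @export
window_depth <- function(bedcov, windows) {
  if (nrow(bedcov) != nrow(windows) ||
      !all(bedcov$start == windows$start & bedcov$end == windows$end &
           bedcov$chrom == windows$chrom))
    tc4_stop("triC4_window_mismatch", "coverage records do not match the window set")
  if (any(bedcov$sum < 0))
    tc4_stop("triC4_bad_counts", "negative coverage sums")
  bedcov$sum / (bedcov$end - bedcov$start)
}

#' Coverage profile of one sample
#'
#' Bundles a sample's per-window mean depths over the MHC windows: all reads
#' (`depth_all`) and uniquely-mapping reads at MAPQ >= 30 (`depth_uniq`).
#' Normalized fields are filled by [normalize_profile()].
#'
#' @param sample_id sample identifier.
#' @param windows window set.
#' @param depth_all,depth_uniq numeric vectors, one value per window.
#' @return list of class `coverage_profile`.
#' @export
coverage_profile <- function(sample_id, windows, depth_all, depth_uniq) {
  n <- nrow(windows)
  if (length(depth_all) != n || length(depth_uniq) != n)
    tc4_stop("triC4_window_mismatch", "depth vector length does not match windows")
  if (any(depth_all < 0) || any(depth_uniq < 0))
    tc4_stop("triC4_bad_counts", "depths must be non-negative")
  structure(list(sample_id = sample_id, windows = windows,
                 depth_all = depth_all, depth_uniq = depth_uniq,
                 norm_all = NULL, norm_uniq = NULL),
            class = "coverage_profile")
}

#' Normalize a coverage profile to the diploid scale
#'
#' Each sample is normalized so that its mean all-read depth over the two
#' 25 kb flanking regions maps to 2.0 (normal diploid): norm = 2 x depth /
#' flank mean. Under this scheme the flank histogram peaks at 2 and the
#' combined C4 region peaks at 1, 1.5 and 2 for total copy numbers 2, 3
#' and 4, since reads from all C4 copies distribute over the two paralogous
#' reference loci.
#'
#' @param profile a [coverage_profile()].
#' @param config a [c4_region_config()].
#' @return the profile with `norm_all`, `norm_uniq` and `flank_mean` filled.
#' @export
normalize_profile <- function(profile, config = c4_region_config()) {
  fl <- windows_in(profile$windows, config$flanks)
  if (length(fl) == 0L)
    tc4_stop("triC4_window_mismatch", "no windows fall in the flanking regions")
  fm <- mean(profile$depth_all[fl])
  if (fm <= 0)
    tc4_stop("triC4_normalization", "flank mean depth is zero; cannot normalize")
  profile$flank_mean <- fm
  profile$norm_all <- 2 * profile$depth_all / fm
  profile$norm_uniq <- 2 * profile$depth_uniq / fm
  profile
}

#' Total C4 copy number from normalized coverage
#'
#' Thresholded assignment on the mean diploid-normalized all-read coverage of
#' the C4 region (HERV excluded): values at or below 1.4 give 2 copies,
#' (1.4, 1.9] gives 3, above 1.9 gives 4. Exact boundary values assign to the
#' lower class (the published rule uses strict inequalities on both sides,
#' leaving boundaries undefined). Values below 0.7 fall outside the observed
#' peaks and are assigned 2 with a QC flag rather than extrapolated.
#'
#' @param c4_norm_all_mean non-negative scalar.
#' @param config a [c4_region_config()].
#' @return list: `total_gcn` (2, 3 or 4), `flags` (character).
#' @export
call_total_gcn <- function(c4_norm_all_mean, config = c4_region_config()) {
  x <- c4_norm_all_mean
  if (is.na(x) || x < 0)
    tc4_stop("triC4_domain", "normalized coverage must be non-negative")
  flags <- character()
  if (x < config$low_total_flag) flags <- "low_total_coverage"
  total <- if (x <= config$gcn2_upper) 2L else if (x <= config$gcn3_upper) 3L else 4L
  list(total_gcn = total, flags = flags)
}

#' Split total C4 copy number into C4A and C4B
#'
#' The published heuristic: a paralog with mean unique-read coverage below
#' the null cut-off (0.04) has 0 copies and the other paralog receives the
#' full total (C4A checked first). Otherwise, total 2 splits 1+1; total 3
#' gives 2 to the paralog with more unique coverage (ties go to C4A); total 4
#' splits 2+2 unless the coverage ratio exceeds 2.5, in which case the
#' higher-coverage paralog gets 3 and the other 1. The split always sums to
#' the total. Both paralogs null is inconsistent with a positive total: the
#' call is (0, total) with a QC flag.
#'
#' @param uniq_a,uniq_b mean normalized unique-read coverage of the C4A/C4B
#'   discriminating regions.
#' @param total_gcn integer in 2..4.
#' @param config a [c4_region_config()].
#' @return list: `gcn_a`, `gcn_b`, `flags`.
#' @export
call_paralog_gcn <- function(uniq_a, uniq_b, total_gcn, config = c4_region_config()) {
  if (uniq_a < 0 || uniq_b < 0)
    tc4_stop("triC4_domain", "unique coverages must be non-negative")
  if (!total_gcn %in% 2:4)
    tc4_stop("triC4_domain", "total_gcn must be 2, 3 or 4")
  a_null <- uniq_a < config$null_cutoff
  b_null <- uniq_b < config$null_cutoff
  flags <- character()
  if (a_null && b_null) {
    flags <- "both_paralogs_null"
    return(list(gcn_a = 0L, gcn_b = as.integer(total_gcn), flags = flags))
  }
  if (a_null) return(list(gcn_a = 0L, gcn_b = as.integer(total_gcn), flags = flags))
  if (b_null) return(list(gcn_a = as.integer(total_gcn), gcn_b = 0L, flags = flags))
  if (total_gcn == 2L) {
    ab <- c(1L, 1L)
  } else if (total_gcn == 3L) {
    ab <- if (uniq_a >= uniq_b) c(2L, 1L) else c(1L, 2L)
  } else {
    ratio <- max(uniq_a, uniq_b) / min(uniq_a, uniq_b)
    ab <- if (ratio > config$ratio_cutoff) {
      if (uniq_a >= uniq_b) c(3L, 1L) else c(1L, 3L)
    } else c(2L, 2L)
  }
  list(gcn_a = ab[1], gcn_b = ab[2], flags = flags)
}

#' Call C4 copy numbers for one coverage profile
#'
#' Composition of [normalize_profile()], [call_total_gcn()] and
#' [call_paralog_gcn()]: total copy number from the all-read C4-region mean
#' (HERV excluded), paralog split from the unique-read discriminating-region
#' means.
#'
#' @param profile a [coverage_profile()]; normalized automatically if not
#'   already.
#' @param config a [c4_region_config()].
#' @return one-row data.frame of class `c4_call`: `sample_id`,
#'   `c4_norm_all`, `uniq_a`, `uniq_b`, `total_gcn`, `gcn_a`, `gcn_b`,
#'   `a_null`, `b_null`, `flags` (';'-joined).
#' @export
call_sample <- function(profile, config = c4_region_config()) {
  if (is.null(profile$norm_all)) profile <- normalize_profile(profile, config)
  w <- profile$windows
  c4_idx <- unlist(lapply(config$c4_intervals, function(iv)
    windows_in(w, list(iv), exclude = config$herv)))
  a_idx <- windows_in(w, list(config$c4a_unique))
  b_idx <- windows_in(w, list(config$c4b_unique))
  if (!length(c4_idx) || !length(a_idx) || !length(b_idx))
    tc4_stop("triC4_window_mismatch", "config regions contain no windows")
  c4_all <- mean(profile$norm_all[c4_idx])
  uniq_a <- mean(profile$norm_uniq[a_idx])
  uniq_b <- mean(profile$norm_uniq[b_idx])
  tot <- call_total_gcn(c4_all, config)
  par <- call_paralog_gcn(uniq_a, uniq_b, tot$total_gcn, config)
  out <- data.frame(sample_id = profile$sample_id, c4_norm_all = c4_all,
                    uniq_a = uniq_a, uniq_b = uniq_b,
                    total_gcn = tot$total_gcn, gcn_a = par$gcn_a,
                    gcn_b = par$gcn_b, a_null = par$gcn_a == 0L,
                    b_null = par$gcn_b == 0L,
                    flags = paste(c(tot$flags, par$flags), collapse = ";"),
                    stringsAsFactors = FALSE)
  class(out) <- c("c4_call", class(out))
  out
}

#' Call C4 copy numbers for a coverage set
#'
#' @param coverage a `coverage_set` from [simulate_coverage()] or
#'   [read_coverage_tsv()], or a list of [coverage_profile()]s.
#' @param config a [c4_region_config()].
#' @return data.frame with one [call_sample()] row per sample.
#' @export
call_c4 <- function(coverage, config = c4_region_config()) {
  profiles <- if (inherits(coverage, "coverage_set"))
    coverage_set_profiles(coverage) else coverage
  out <- do.call(rbind, lapply(profiles, call_sample, config = config))
  rownames(out) <- NULL
  out
}

# explode a coverage_set (windows + depth matrices) into per-sample profiles
coverage_set_profiles <- function(cs) {
  lapply(seq_along(cs$sample_ids), function(i)
    coverage_profile(cs$sample_ids[i], cs$windows,
                     cs$depth_all[i, ], cs$depth_uniq[i, ]))
}

#' Read a long-format windowed coverage TSV
#'
#' Expected columns: `sample_id`, `chrom`, `start`, `end`, `sum_all`,
#' `sum_uniq` -- the layout written by [write_fixture_bundle()], i.e. one
#' `samtools bedcov` record per window carrying both MAPQ classes.
#'
#' @param path TSV path.
#' @param windows window set the records must tile.
#' @return a `coverage_set` (sample_ids, windows, depth matrices).
#' @export
read_coverage_tsv <- function(path, windows) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "sum_all", "sum_uniq")
  if (!all(need %in% names(x)))
    tc4_stop("triC4_window_mismatch",
             paste("coverage TSV must have columns:", paste(need, collapse = ", ")))
  ids <- unique(x$sample_id)
  n <- nrow(windows)
  da <- matrix(NA_real_, length(ids), n)
  du <- matrix(NA_real_, length(ids), n)
  for (i in seq_along(ids)) {
    xi <- x[x$sample_id == ids[i], ]
    xi <- xi[order(xi$start), ]
    da[i, ] <- window_depth(data.frame(chrom = xi$chrom, start = xi$start,
                                       end = xi$end, sum = xi$sum_all), windows)
    du[i, ] <- window_depth(data.frame(chrom = xi$chrom, start = xi$start,
                                       end = xi$end, sum = xi$sum_uniq), windows)
  }
  structure(list(sample_ids = ids, windows = windows,
                 depth_all = da, depth_uniq = du),
            class = "coverage_set")
}
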