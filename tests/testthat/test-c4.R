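test_that("window_depth converts bedcov sums to mean depth", {
  w <- mhc_windows(0, 3000)
  bc <- data.frame(chrom = "chr6", start = w$start, end = w$end,
                   sum = c(30000, 0, 12345))
  expect_equal(window_depth(bc, w), c(30, 0, 12.345))
  bad <- bc; bad$start[2] <- bad$start[2] + 1
  expect_error(window_depth(bad, w), class = "triC4_window_mismatch")
  # Poisson(30) per-base coverage over one 1 kb window: mean within 30 +/- 1
  set.seed(1)
  s <- sum(rpois(1000, 30))
  d <- window_depth(data.frame(chrom = "chr6", start = 0, end = 1000, sum = s),
                    mhc_windows(0, 1000))
  expect_lt(abs(d - 30), 1)
})

test_that("normalize_profile puts flanks on the diploid scale", {
  cfg <- c4_region_config()
  w <- mhc_windows()
  # uniform 30x everywhere: flank mean 30, everything maps to 2.0
  p <- coverage_profile("s1", w, rep(30, nrow(w)), rep(30, nrow(w)))
  p <- normalize_profile(p, cfg)
  expect_equal(p$flank_mean, 30)
  expect_equal(unique(p$norm_all), 2)
  # halved C4-region depth -> norm 1.0 (a 2-copy sample's peak)
  depth <- rep(30, nrow(w))
  c4w <- unlist(lapply(cfg$c4_intervals, function(iv)
    which((w$start + w$end) / 2 >= iv[1] & (w$start + w$end) / 2 < iv[2])))
  depth[c4w] <- 15
  p2 <- normalize_profile(coverage_profile("s2", w, depth, depth), cfg)
  expect_equal(unique(p2$norm_all[c4w]), 1)
  # flank mean 40, unique-region depth 6 -> norm 0.3 (the 1-copy unique peak)
  expect_equal(2 * 6 / 40, 0.3)
  p3 <- normalize_profile(coverage_profile("s3", w, rep(40, nrow(w)),
                                           rep(6, nrow(w))), cfg)
  expect_equal(unique(p3$norm_uniq), 0.3)
  expect_error(normalize_profile(
    coverage_profile("s0", w, rep(0, nrow(w)), rep(0, nrow(w))), cfg),
    class = "triC4_normalization")
})

test_that("call_total_gcn applies the published peak thresholds", {
  expect_equal(call_total_gcn(0.95)$total_gcn, 2)
  expect_equal(call_total_gcn(1.55)$total_gcn, 3)
  expect_equal(call_total_gcn(2.10)$total_gcn, 4)
  # boundaries assign to the lower class; sub-0.7 values flagged not extrapolated
  expect_equal(call_total_gcn(1.4)$total_gcn, 2)
  expect_equal(call_total_gcn(1.9)$total_gcn, 3)
  low <- call_total_gcn(0.5)
  expect_equal(low$total_gcn, 2)
  expect_equal(low$flags, "low_total_coverage")
  expect_error(call_total_gcn(-0.1), class = "triC4_domain")
  # monotone non-decreasing over a grid
  grid <- seq(0, 3, by = 0.01)
  tot <- vapply(grid, function(x) call_total_gcn(x)$total_gcn, integer(1))
  expect_true(all(diff(tot) >= 0))
})

test_that("call_paralog_gcn implements the published heuristic exactly", {
  get <- function(a, b, t) {
    r <- call_paralog_gcn(a, b, t)
    c(r$gcn_a, r$gcn_b)
  }
  expect_equal(get(0.01, 0.58, 2), c(0, 2))   # C4A null takes the total
  expect_equal(get(0.30, 0.29, 2), c(1, 1))
  expect_equal(get(0.61, 0.30, 3), c(2, 1))
  expect_equal(get(0.90, 0.30, 4), c(3, 1))   # ratio 3 > 2.5
  expect_equal(get(0.58, 0.60, 4), c(2, 2))   # ratio below cut-off
  expect_equal(get(0.58, 0.01, 3), c(3, 0))   # B null mirrors
  both <- call_paralog_gcn(0.01, 0.02, 2)
  expect_equal(both$flags, "both_paralogs_null")
  expect_equal(both$gcn_a + both$gcn_b, 2)
  expect_error(call_paralog_gcn(-1, 0.3, 2), class = "triC4_domain")
  expect_error(call_paralog_gcn(0.3, 0.3, 5), class = "triC4_domain")
})

test_that("paralog split always sums to the total and is A/B symmetric", {
  grid <- seq(0, 1.2, by = 0.06)
  for (t in 2:4) for (a in grid) for (b in grid) {
    r <- call_paralog_gcn(a, b, t)
    expect_identical(r$gcn_a + r$gcn_b, as.integer(t))
    # symmetry under swap, except the order-specified A-null-first branch
    if (!(a < 0.04 && b < 0.04)) {
      s <- call_paralog_gcn(b, a, t)
      if (a != b) expect_identical(c(r$gcn_a, r$gcn_b), c(s$gcn_b, s$gcn_a))
    }
  }
})

test_that("call_sample recovers simulated copy numbers through the full path", {
  cfg <- small_config(n = 60)
  # noiseless coverage: exact recovery for every subject
  cfg0 <- sim_config(n_subjects = 60, coverage = list(noise_cv = 1e-8))
  geno <- sample_genotypes(cfg0, seed = 21)
  cs <- simulate_coverage(geno, cfg0, seed = 21)
  calls <- call_c4(cs)
  expect_equal(calls$total_gcn, geno$total_gcn)
  expect_equal(calls$gcn_a, geno$gcn_a)
  expect_equal(calls$gcn_b, geno$gcn_b)
  # a C4A-deleted two-copy sample shows the published signature
  two <- data.frame(subject_id = "x", gcn_a = 0, gcn_b = 2)
  cs2 <- simulate_coverage(two, cfg0, seed = 3)
  p <- normalize_profile(triC4:::coverage_set_profiles(cs2)[[1]], c4_region_config())
  call <- call_sample(p)
  expect_equal(c(call$total_gcn, call$gcn_a, call$gcn_b), c(2, 0, 2))
  expect_lt(call$uniq_a, 0.04)
  expect_equal(call$c4_norm_all, 1.0, tolerance = 0.02)
  # balanced four-copy sample
  four <- data.frame(subject_id = "y", gcn_a = 2, gcn_b = 2)
  call4 <- call_c4(simulate_coverage(four, cfg0, seed = 4))
  expect_equal(c(call4$total_gcn, call4$gcn_a, call4$gcn_b), c(4, 2, 2))
})
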