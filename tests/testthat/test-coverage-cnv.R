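flat_alignments <- function(positions, rl = 50L) {
  n <- length(positions)
  data.frame(qname = sprintf("r%03d", seq_len(n)), flag = rep(0L, n),
             pos = as.integer(positions), mapq = rep(60L, n),
             cigar = rep(sprintf("%dM", rl), n), mpos = rep(0L, n),
             tlen = rep(0L, n), seq = rep(NA_character_, n))
}

test_that("depth counts covering records, brute-force checked", {
  ## two 50-bp reads overlapping by 30 bp
  a <- flat_alignments(c(100, 120))
  dp <- depth_profile(a, 300)
  oracle <- integer(300)
  for (p in 101:150) oracle[p] <- oracle[p] + 1L
  for (p in 121:170) oracle[p] <- oracle[p] + 1L
  expect_identical(dp$depth, oracle)
  expect_identical(sum(dp$depth == 2L), 30L)
  ## no reads -> zeros
  expect_identical(depth_profile(flat_alignments(integer(0)), 100)$depth,
                   integer(100))
  expect_error(depth_profile(flat_alignments(280), 300), "bounds")
})

test_that("depth excludes unmapped and duplicate-flagged records", {
  a <- flat_alignments(c(10, 10, 10))
  a$flag <- c(0L, 4L, 1024L)
  dp <- depth_profile(a, 100)
  expect_identical(max(dp$depth), 1L)
  expect_identical(dp$total_mapped, 1L)
})

test_that("uniform simulated depth is recovered within 2%", {
  g <- small_genome()
  cfg <- small_config()
  means <- sapply(1:5, function(s) {
    a <- simulate_reads(g, cfg, seed = 600 + s, depth = 100)
    mean(depth_profile(a, g$length)$depth)
  })
  expect_lt(abs(mean(means) - 100) / 100, 0.02)
})

test_that("CPMM follows its formula and windows tile the genome", {
  g <- small_genome()
  ## constant depth 10 from 1e6 mapped reads -> CPMM 10 in every window
  dp <- structure(list(depth = rep(10L, g$length), total_mapped = 1000000L),
                  class = "depth_profile")
  cw <- cpmm_windows(dp, g)
  expect_true(all(abs(cw$cpmm - 10) < 1e-9))
  expect_identical(cw$windows$start[1], 0L)
  expect_identical(cw$windows$end[nrow(cw$windows)], g$length)
  expect_true(all(diff(cw$windows$start) == 500L))
  expect_error(cpmm_windows(structure(list(depth = rep(0L, g$length),
                                           total_mapped = 0L),
                                      class = "depth_profile"), g),
               "zero mapped")
})

test_that("window exclusions cover edges, partial windows and mtpt overlap", {
  seqs <- random_dna_fixture(5250)
  ## mtpt sharing exactly 1 bp with window 3 ([1000,1500)): interval [1499,1600)
  g <- annotated_genome(seqs, mtpt = data.frame(start = 1499, end = 1600))
  dp <- structure(list(depth = rep(5L, 5250), total_mapped = 1000L),
                  class = "depth_profile")
  cw <- cpmm_windows(dp, g)
  w <- cw$windows
  expect_true(w$excluded[1])
  expect_true(w$excluded[nrow(w)])             # trailing 250-bp partial
  expect_match(w$reason[nrow(w)], "partial")
  expect_true(w$excluded[3] && grepl("mtpt", w$reason[3]))
  expect_true(w$excluded[4])                   # [1500,2000) overlaps [1499,1600)
  expect_false(w$excluded[5])
})

test_that("CPMM is invariant to duplicating every read", {
  g <- small_genome()
  cfg <- small_config()
  a <- simulate_reads(g, cfg, seed = 5, depth = 30)
  a2 <- rbind(a, transform(a, qname = paste0(qname, "b")))
  c1 <- cpmm_windows(depth_profile(a, g$length), g)
  c2 <- cpmm_windows(depth_profile(a2, g$length), g)
  expect_equal(c1$cpmm, c2$cpmm, tolerance = 1e-12)
})

test_that("aligned bases bound the depth mass over retained windows", {
  g <- small_genome()
  a <- simulate_reads(g, small_config(), seed = 9, depth = 20)
  dp <- depth_profile(a, g$length)
  cw <- cpmm_windows(dp, g)
  keep <- !cw$windows$excluded
  win_mean_depth <- cw$cpmm * dp$total_mapped / 1e6
  mass <- sum(win_mean_depth[keep] * (cw$windows$end - cw$windows$start)[keep])
  total_aligned <- sum(cigar_width_fixture(a$cigar))
  expect_lte(mass, total_aligned)
})

test_that("composition model reproduces exact linear structure", {
  set.seed(3)
  gc <- runif(40, 0.3, 0.6); hp <- rpois(40, 2)
  ## exact construction: cpmm = 2 + 3*gc
  fit <- suppressWarnings(composition_model(2 + 3 * gc, gc, hp))
  expect_equal(unname(fit$coefficients["gc"]), 3, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  expect_true(all(abs(fit$residuals) < 1e-8))
  ## constant response: zero slopes, zero residuals
  fit0 <- composition_model(rep(5, 40), gc, hp)
  expect_true(all(abs(fit0$residuals) < 1e-10))
  ## constant predictor dropped with a warning
  expect_warning(composition_model(rnorm(40), rep(0.5, 40), hp), "dropped")
})

test_that("planted GC effect is recovered with the right sign", {
  cfg <- sim_config(gc_effect = 2, depth = 200)
  hits <- 0L
  n_seed <- 40L
  for (s in seq_len(n_seed)) {
    wm <- simulate_window_profiles(cfg, seed = 3000 + s, n_windows = 40)
    keep <- !wm$windows$excluded
    fit <- composition_model(colMeans(wm$cpmm)[keep], wm$windows$gc[keep],
                             wm$windows$homopolymers[keep])
    hits <- hits + (unname(fit$coefficients["gc"]) > 0)
  }
  expect_gte(hits / n_seed, 0.95)
})

test_that("spatial runs test flags autocorrelation and passes white noise", {
  cfg <- sim_config()
  ## smoothed baseline -> far fewer crossings than expected
  wm <- simulate_window_profiles(sim_config(baseline_amplitude = 0.4,
                                            n_shifted_windows = 0L),
                                 seed = 5, n_windows = 80)
  r <- spatial_runs_test(wm)
  expect_lt(r$observed_crossings, r$expected_crossings)
  expect_lt(r$p_value, 0.001)
  ## white-noise windows: observed within 2 SD of expectation most of the time
  set.seed(42)
  ok <- 0L
  for (i in 1:60) {
    vals <- rnorm(80)
    rt <- runs_test(vals)
    ok <- ok + (abs(rt$observed_crossings - rt$expected_crossings) <=
                  2 * sqrt(rt$variance))
  }
  expect_gte(ok / 60, 0.90)
})

test_that("divergence scan is degenerate-safe and ranks shifted windows first", {
  lab <- ma_labels()
  ## identical samples: no significant windows
  cpmm <- matrix(rep(seq(100, 139), each = 18), nrow = 18)
  win <- data.frame(window = 1:40, start = (0:39) * 500, end = (1:40) * 500,
                    gc = runif(40, 0.4, 0.5), homopolymers = 0L,
                    excluded = FALSE, reason = "")
  wm <- structure(list(windows = win, cpmm = cpmm,
                       samples = paste0("s", 1:18)),
                  class = "window_matrix")
  scan <- window_divergence_scan(wm, lab$treatment, lab$line)
  expect_identical(sum(scan$significant), 0L)
  expect_true(all(scan$method == "degenerate"))
  expect_true(all(scan$ratio == 1))
  ## adjusted p never below raw p
  wm2 <- simulate_window_profiles(sim_config(), seed = 8, n_windows = 30)
  tr <- attr(wm2, "truth")
  scan2 <- window_divergence_scan(wm2, tr$samples$treatment, tr$samples$line)
  expect_true(all(scan2$treatment_p_adj >= scan2$treatment_p - 1e-12))
  ## lowering the FDR threshold never adds significant windows
  scan_strict <- window_divergence_scan(wm2, tr$samples$treatment,
                                        tr$samples$line, fdr = 0.01)
  expect_true(all(scan_strict$window[scan_strict$significant] %in%
                    scan2$window[scan2$significant]))
})

test_that("read-level round trip recovers the planted window profile", {
  cfg <- small_config(n_mtpt = 0L)
  g <- build_toy_genome(cfg, seed = 55)
  n_win <- g$length %/% 500L
  set.seed(61)
  rs <- sapply(1:5, function(s) {
    mult <- exp(rnorm(n_win, 0, 0.25))
    a <- simulate_reads(g, cfg, seed = 700 + s, multipliers = mult, depth = 100)
    cw <- cpmm_windows(depth_profile(a, g$length), g)
    keep <- !cw$windows$excluded
    cor(cw$cpmm[keep], mult[keep])
  })
  expect_gte(mean(rs), 0.9)
})

test_that("treatment ratio recovers a planted shift on a window block", {
  cfg <- small_config(n_mtpt = 0L, shift = 1.205, n_shifted_windows = 4L,
                      depth = 150)
  ratios <- sapply(1:8, function(s) {
    wm <- simulate_window_profiles(cfg, seed = 900 + s, n_windows = 40)
    tr <- attr(wm, "truth")
    scan <- window_divergence_scan(wm, tr$samples$treatment, tr$samples$line)
    mean(scan$ratio[scan$window %in% tr$shifted])
  })
  ## the per-million normalisation spreads a planted molecular shift over
  ## the whole profile: with 4 of 40 windows shifted the expected CPMM
  ## ratio is shift / (1 + 0.1 (shift - 1))
  target <- 1.205 / (1 + 4 / 40 * 0.205)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - target), 2 * se + 0.01)
  ## and it stays within ~3% of the planted molecular shift itself
  expect_lt(abs(mean(ratios) - 1.205) / 1.205, 0.03)
})

test_that("coverage correlation behaves on identical, anti- and independent profiles", {
  wm1 <- simulate_window_profiles(sim_config(n_shifted_windows = 0L),
                                  seed = 21, n_windows = 30)
  expect_equal(coverage_correlation(wm1, wm1), 1)
  ## anti-correlated construction
  wm2 <- wm1
  keep <- !wm1$windows$excluded
  wm2$cpmm <- matrix(rep(2 * mean(wm1$cpmm) - colMeans(wm1$cpmm),
                         each = nrow(wm1$cpmm)), nrow = nrow(wm1$cpmm))
  expect_equal(coverage_correlation(wm1, wm2), -1, tolerance = 1e-9)
  ## independent profiles: small |r| most of the time
  set.seed(9)
  ok <- 0L
  for (i in 1:40) {
    a <- simulate_window_profiles(sim_config(n_shifted_windows = 0L,
                                             baseline_amplitude = 0.05,
                                             baseline_scale = 2L),
                                  seed = 5000 + 2 * i, n_windows = 100)
    b <- simulate_window_profiles(sim_config(n_shifted_windows = 0L,
                                             baseline_amplitude = 0.05,
                                             baseline_scale = 2L),
                                  seed = 5001 + 2 * i, n_windows = 100)
    ok <- ok + (abs(coverage_correlation(a, b)) < 0.3)
  }
  expect_gte(ok / 40, 0.90)
  ## constant profile flagged undefined
  wc <- wm1; wc$cpmm[] <- 3
  expect_warning(r <- coverage_correlation(wc, wc), "undefined")
  expect_true(is.na(r))
})
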