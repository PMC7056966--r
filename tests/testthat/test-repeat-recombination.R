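# exhaustive oracle: all-vs-all comparison of fixed-length substrings,
# feasible on a ~2-kb sequence
oracle_has_repeat <- function(seqs, len, min_ident) {
  v <- strsplit(seqs, "")[[1]]
  n <- length(v)
  for (i in seq_len(n - 2 * len)) {
    for (j in seq(i + len, n - len + 1L)) {
      if (mean(v[i:(i + len - 1L)] == v[j:(j + len - 1L)]) >= min_ident)
        return(TRUE)
    }
  }
  FALSE
}

plant_genome <- function(L, plant_fun = NULL, seed = 1) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  if (!is.null(plant_fun)) s <- plant_fun(s)
  s
}

test_that("random sequence yields no in-range repeat pairs", {
  s <- plant_genome(20000, seed = 2)
  rp <- find_repeat_pairs(s)
  expect_identical(sum(rp$in_range), 0L)
  ## exhaustive cross-check on a 2-kb slice: no 100-bp pair at >= 80%
  sub <- substr(s, 1, 2000)
  expect_false(oracle_has_repeat(sub, 100, 0.80))
})

test_that("a planted 300-bp copy at 85% identity is located within 5 bp", {
  unit <- plant_genome(300, seed = 3)
  mutated <- local({
    set.seed(4)
    v <- strsplit(unit, "")[[1]]
    hit <- sample(300, 45)   # 15% divergence
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  })
  g <- plant_genome(20000, seed = 5, plant_fun = function(s) {
    substr(s, 3001, 3300) <- unit
    substr(s, 12001, 12300) <- mutated
    s
  })
  rp <- find_repeat_pairs(g)
  rp <- rp[rp$in_range, ]
  expect_identical(nrow(rp), 1L)
  expect_lte(abs(rp$copy1_start - 3000), 5)
  expect_lte(abs(rp$copy2_start - 12000), 5)
  expect_gte(rp$identity, 0.80)
  expect_identical(rp$orientation, "direct")
})

test_that("an identical 600-bp duplication is reported but flagged out of range", {
  unit <- plant_genome(600, seed = 6)
  g <- plant_genome(20000, seed = 7, plant_fun = function(s) {
    substr(s, 2001, 2600) <- unit
    substr(s, 9001, 9600) <- unit
    s
  })
  rp <- find_repeat_pairs(g)
  long <- rp[rp$length >= 550, ]
  expect_identical(nrow(long), 1L)
  expect_false(long$in_range)
})

test_that("inverted repeats are found with mirrored coordinates", {
  unit <- plant_genome(200, seed = 8)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
  g <- plant_genome(15000, seed = 9, plant_fun = function(s) {
    substr(s, 4001, 4200) <- unit
    substr(s, 11001, 11200) <- rc
    s
  })
  rp <- find_repeat_pairs(g)
  inv <- rp[rp$orientation == "inverted" & rp$in_range, ]
  expect_gte(nrow(inv), 1L)
  expect_lte(abs(inv$copy1_start[1] - 4000), 5)
  expect_lte(abs(inv$copy2_start[1] - 11000), 5)
})

test_that("discovery is mirror-consistent under reverse complement", {
  g <- build_toy_genome(small_config(n_repeats = 2L), seed = 33)
  L <- g$length
  rp <- find_repeat_pairs(g)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$sequence)))
  rp_rc <- find_repeat_pairs(rc)
  expect_identical(nrow(rp_rc), nrow(rp))
  ## mirrored coordinates: copy intervals map to (L - end, L - start)
  mirrored <- data.frame(
    copy1_start = L - rp$copy2_end, copy1_end = L - rp$copy2_start,
    copy2_start = L - rp$copy1_end, copy2_end = L - rp$copy1_start)
  ord1 <- order(rp_rc$copy1_start)
  ord2 <- order(mirrored$copy1_start)
  expect_equal(rp_rc$copy1_start[ord1], mirrored$copy1_start[ord2],
               tolerance = 1e-9)
  expect_identical(rp_rc$orientation[ord1], rp$orientation[ord2])
})

## a canonical direct repeat pair for geometry tests
rp_fix <- data.frame(copy1_start = 2000L, copy1_end = 2150L,
                     copy2_start = 6000L, copy2_end = 6150L,
                     orientation = "direct", length = 150L,
                     identity = 0.9, in_range = TRUE)

test_that("read-pair geometry identifies parental and recombinant pairs", {
  im <- 245; isd <- 30
  ## parental copy 1: fwd mate anchored 50 bp before the copy (reading into
  ## it), rev mate ending 45 bp past the copy; insert at the model mean
  f_pos <- 2000L - 50L
  r_end <- f_pos + 245L                      # = 2195, 45 bp past copy1 end
  expect_identical(
    classify_read_pair(f_pos, "+", 90L, r_end - 90L, "-", 90L,
                       rp_fix, im, isd),
    "parental_copy1")
  ## same geometry at copy 2
  expect_identical(
    classify_read_pair(6000L - 50L, "+", 90L, 6000L - 50L + 245L - 90L, "-", 90L,
                       rp_fix, im, isd),
    "parental_copy2")
  ## recombinant AB: fwd mate before copy1, rev mate in the right flank of
  ## copy2; junction-implied insert = 95 + 150 + 0 -> place mate end at
  ## copy2_end + (245 - 95 - 150) = copy2_end
  r2_end <- 6150L + (245L - 95L - 150L)
  expect_identical(
    classify_read_pair(f_pos, "+", 90L, r2_end - 90L + 10L, "-", 90L,
                       rp_fix, im, isd) %in% c("recombinant_AB"),
    TRUE)
  ## recombinant BA: fwd mate before copy2, rev mate after copy1
  expect_identical(
    classify_read_pair(6000L - 95L, "+", 90L, 2150L + 5L, "-", 90L,
                       rp_fix, im, isd),
    "recombinant_BA")
  ## both mates inside copy 1 -> uninformative
  expect_identical(
    classify_read_pair(2010L, "+", 90L, 2050L, "-", 90L, rp_fix, im, isd),
    "uninformative")
  ## far away -> uninformative
  expect_identical(
    classify_read_pair(100L, "+", 90L, 400L, "-", 90L, rp_fix, im, isd),
    "uninformative")
})

test_that("inverted-repeat junctions require same-strand mates", {
  rp_inv <- rp_fix; rp_inv$orientation <- "inverted"
  im <- 245; isd <- 30
  ## junction A: both mates forward, anchored in the two left flanks;
  ## implied insert = (s1 - f) + 150 + (s2 - r)
  f_pos <- 2000L - 60L; r_pos <- 6000L - 35L
  expect_identical(
    classify_read_pair(f_pos, "+", 50L, r_pos, "+", 50L, rp_inv, im, isd),
    "recombinant_AB")
  ## junction B: both mates reverse, anchored in the two right flanks
  expect_identical(
    classify_read_pair(2150L + 10L, "-", 50L, 6150L + 25L, "-", 50L,
                       rp_inv, im, isd),
    "recombinant_BA")
  ## the same positions with FR orientation are not a junction
  expect_identical(
    classify_read_pair(f_pos, "+", 50L, r_pos, "-", 50L, rp_inv, im, isd),
    "uninformative")
})

test_that("classification is symmetric under swapping copy labels", {
  swapped <- rp_fix
  swapped[c("copy1_start", "copy1_end")] <- rp_fix[c("copy2_start", "copy2_end")]
  swapped[c("copy2_start", "copy2_end")] <- rp_fix[c("copy1_start", "copy1_end")]
  swap_map <- c(parental_copy1 = "parental_copy2",
                parental_copy2 = "parental_copy1",
                recombinant_AB = "recombinant_BA",
                recombinant_BA = "recombinant_AB",
                uninformative = "uninformative")
  set.seed(17)
  for (i in 1:300) {
    pos1 <- sample(1500:6500, 1); pos2 <- pos1 + sample(50:400, 1)
    st <- sample(c("+", "-"), 2, replace = TRUE)
    a <- classify_read_pair(pos1, st[1], 90L, pos2, st[2], 90L, rp_fix, 245, 30)
    b <- classify_read_pair(pos1, st[1], 90L, pos2, st[2], 90L, swapped, 245, 30)
    expect_identical(b, unname(swap_map[a]))
  }
})

test_that("recombinant fractions carry Wilson intervals and flag empty pairs", {
  counts <- data.frame(pair = 1:3, parental = c(100L, 0L, 90L),
                       recombinant = c(0L, 0L, 10L),
                       recombinant_AB = c(0L, 0L, 6L),
                       recombinant_BA = c(0L, 0L, 4L))
  r <- recombinant_fraction(counts)
  expect_equal(r$fraction, c(0, NA, 0.1))
  expect_true(is.na(r$ci_lo[2]))
  expect_lt(r$ci_lo[3], 0.1); expect_gt(r$ci_hi[3], 0.1)
  ## interval matches the Wilson closed form
  z <- qnorm(0.975); p <- 0.1; n <- 100
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(r$ci_lo[3], lo, tolerance = 1e-9)
})

test_that("reference-only reads give recombinant fractions consistent with zero", {
  g <- build_toy_genome(small_config(n_repeats = 2L), seed = 44)
  cfg <- small_config(n_repeats = 2L)
  rp <- attr(g, "truth")$repeats
  for (s in 1:3) {
    a <- simulate_reads(g, cfg, seed = 800 + s, depth = 80,
                        recombinant_fractions = c(0, 0))
    cc <- count_conformations(a, rp, cfg$insert_mean, cfg$insert_sd)
    r <- recombinant_fraction(cc)
    expect_true(all(r$recombinant == 0L))
    ## lower bound of the interval includes zero
    expect_true(all(r$ci_lo[r$informative > 0] < 1e-9))
  }
})

test_that("a planted 10% recombinant fraction is recovered within binomial bounds", {
  g <- build_toy_genome(small_config(n_repeats = 1L), seed = 45)
  cfg <- small_config(n_repeats = 1L)
  rp <- attr(g, "truth")$repeats
  inside <- 0L; n_seed <- 12L
  for (s in seq_len(n_seed)) {
    a <- simulate_reads(g, cfg, seed = 900 + s, depth = 120,
                        recombinant_fractions = 0.10)
    r <- recombinant_fraction(count_conformations(a, rp, cfg$insert_mean,
                                                  cfg$insert_sd))
    inside <- inside + (!is.na(r$fraction) && r$ci_lo <= 0.10 && r$ci_hi >= 0.10)
  }
  expect_gte(inside / n_seed, 0.75)
})

test_that("recombination scan flags a treatment-dependent repeat pair", {
  lab <- ma_labels()
  set.seed(23)
  detected <- 0L; n_seed <- 15L
  for (s in seq_len(n_seed)) {
    ## 5 repeat pairs; pair 3 fraction differs by treatment (0.05 vs 0.15)
    fr <- sapply(1:5, function(p) {
      base <- if (p == 3) ifelse(lab$treatment == "salt", 0.15, 0.05) else 0.05
      rbinom(18, 200, base) / 200
    })
    scan <- recombination_divergence_scan(fr, lab$treatment, lab$line)
    detected <- detected + (scan$significant[3] &&
                              sum(scan$significant[-3]) == 0L)
  }
  expect_gte(detected / n_seed, 0.8)
  ## identical fractions everywhere: nothing significant
  flat <- matrix(0.07, 18, 4)
  scan0 <- recombination_divergence_scan(flat, lab$treatment, lab$line)
  expect_identical(sum(scan0$significant), 0L)
})
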