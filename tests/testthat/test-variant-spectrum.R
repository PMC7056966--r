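make_vs <- function(pos0, ref, alt1, GT, DP = NULL, AD = NULL, alt2 = NULL,
                    vclass = NULL) {
  GT <- as.matrix(GT)
  if (is.null(DP)) DP <- matrix(100L, nrow(GT), ncol(GT))
  variant_set(pos0, ref, alt1, alt2 = alt2, vclass = vclass, GT = GT, DP = DP,
              AD_ALT = AD)
}

test_that("coverage filter applies the depth floor and median band", {
  ## median 100: depths 49, 150, 301 -> removed, kept, removed
  vs <- make_vs(c(10, 20, 30), rep("A", 3), rep("G", 3),
                GT = matrix(1L, 3, 2),
                DP = matrix(c(49, 150, 301), 3, 2))
  f <- filter_variants(vs, median_coverage = 100)
  expect_identical(f$pos0, 20L)
  ## boundary: exactly 50 and exactly the band edges are kept
  vs2 <- make_vs(c(1, 2, 3), rep("A", 3), rep("G", 3), GT = matrix(1L, 3, 1),
                 DP = matrix(c(50, 300, 49), 3, 1))
  expect_identical(filter_variants(vs2, 100)$pos0, c(1L, 2L))
})

test_that("coverage filter is idempotent and returns a subset", {
  g <- small_genome()
  sim <- simulate_population_variants(g, small_config(), seed = 2)
  f1 <- filter_variants(sim$variants, 100)
  f2 <- filter_variants(f1, 100)
  expect_true(all(f1$pos0 %in% sim$variants$pos0))
  expect_identical(f1$pos0, f2$pos0)
  expect_identical(f1$GT, f2$GT)
  ## empty input passes through
  e <- subset_empty <- filter_variants(make_vs(integer(), character(),
                                               character(),
                                               GT = matrix(NA_integer_, 0, 2)), 100)
  expect_identical(e$n_sites, 0L)
})

test_that("MAF polarization marks the minor allele derived and ties unpolarized", {
  gt <- rbind(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),  # 0.9 / 0.1
              c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L))  # 0.5 / 0.5
  vs <- make_vs(c(5, 9), c("G", "A"), c("A", "C"), GT = gt)
  pol <- polarize_by_maf(vs)
  expect_identical(pol$derived[1], "A")
  expect_identical(pol$ancestral[1], "G")
  expect_identical(pol$method[2], "unpolarized")
})

test_that("triallelic sites polarize highest-frequency allele as ancestral", {
  gt <- matrix(c(0L, 0L, 0L, 0L, 1L, 1L, 2L, NA), nrow = 1)
  vs <- make_vs(7, "G", "A", GT = gt, alt2 = "T", vclass = "SNP")
  pol <- polarize_by_maf(vs)
  expect_identical(nrow(pol), 2L)
  expect_setequal(pol$derived, c("A", "T"))
  expect_true(all(pol$ancestral == "G"))
})

test_that("outgroup projection walks gapped alignments correctly", {
  ## reference AAACCGTT aligned with a 3-bp outgroup insertion after pos 2
  blk <- alignment_block(ref_start = 100, out_start = 50,
                         ref_aln = "AAA---CCGTT", out_aln = "AAATTTCCGAT")
  blk$length <- 400; blk$identity <- 0.95   # qualify the block for the test
  ## ref position 106 (0-based; the 7th ref base, T) -> outgroup base A
  vs <- make_vs(106, "T", "C", GT = matrix(c(0L, 0L, 1L), 1))
  pol <- polarize_by_outgroup(vs, blk)
  expect_identical(pol$method, "unpolarized")   # outgroup A matches neither
  ## ref position 105 (G) -> outgroup G: ref allele ancestral
  vs2 <- make_vs(105, "G", "A", GT = matrix(c(0L, 0L, 1L), 1))
  pol2 <- polarize_by_outgroup(vs2, blk)
  expect_identical(pol2$method, "outgroup")
  expect_identical(pol2$ancestral, "G")
  expect_identical(pol2$derived, "A")
  ## position in no qualifying block
  vs3 <- make_vs(500, "A", "G", GT = matrix(c(0L, 1L), 1))
  expect_identical(polarize_by_outgroup(vs3, blk)$method, "unpolarized")
  ## conflicting overlapping blocks
  blk2 <- blk; blk2$out_aln <- "AAATTTCCAAT"   # pos 105 now reads A
  both <- rbind(blk, blk2)
  pol4 <- polarize_by_outgroup(vs2, both)
  expect_identical(pol4$method, "unpolarized")
  expect_true(pol4$conflict)
})

test_that("short or diverged alignment blocks are rejected for polarization", {
  blk <- alignment_block(0, 0, "ACGT", "ACGT")   # 4 bp, identity 1
  vs <- make_vs(1, "C", "T", GT = matrix(c(0L, 1L), 1))
  expect_identical(polarize_by_outgroup(vs, blk)$method, "unpolarized")
})

test_that("polarization agreement counts sites with matching derived calls", {
  a <- data.frame(site = 1:4, pos0 = 1:4, ancestral = "A",
                  derived = c("G", "G", "C", "T"), method = "maf",
                  conflict = FALSE)
  b <- a; b$derived <- c("G", "G", "T", "C"); b$method <- "outgroup"
  expect_equal(polarization_agreement(a, b)$agreement, 0.5)
  expect_equal(polarization_agreement(a, a)$agreement, 1)
  none <- a; none$method <- "unpolarized"
  expect_warning(r <- polarization_agreement(a, none), "no sites")
  expect_true(is.na(r$agreement))
})

test_that("mutation spectrum tallies direction, ts/tv and AT gain", {
  pol <- data.frame(site = 1:4, pos0 = 1:4,
                    ancestral = c("G", "C", "A", "T"),
                    derived = c("A", "T", "C", "A"),
                    method = "maf", conflict = FALSE)
  sp <- mutation_spectrum(pol)
  expect_identical(sp$transitions, 2L)      # G->A, C->T
  expect_identical(sp$transversions, 2L)    # A->C, T->A
  expect_identical(sp$at_gaining, 2L)
  expect_identical(sp$at_losing, 1L)
  expect_identical(sp$at_neutral, 1L)
  expect_equal(sp$at_bias_ratio, 2)
  expect_equal(sum(sp$directional), 4L)
  expect_equal(sum(sp$pair_classes), 4L)
  ## single G->A is a transition and AT-gaining by definition
  one <- mutation_spectrum(pol[1, ])
  expect_identical(one$transitions, 1L)
  expect_identical(one$at_gaining, 1L)
  ## empty set: zero table, undefined ratios
  empty <- mutation_spectrum(pol[0, ])
  expect_equal(sum(empty$directional), 0L)
  expect_true(is.na(empty$at_bias_ratio))
  expect_true(is.na(empty$ts_tv_ratio))
})

test_that("spectrum counts sum to the number of polarized records", {
  g <- small_genome()
  sim <- simulate_population_variants(g, small_config(), seed = 3)
  pol <- polarize_by_maf(sim$variants)
  sp <- mutation_spectrum(pol)
  expect_equal(sum(sp$directional), sum(pol$method != "unpolarized"))
  expect_equal(sp$transitions + sp$transversions, sp$n)
  expect_equal(sp$at_gaining + sp$at_losing + sp$at_neutral, sp$n)
})

test_that("density table matches generator truth and partition site totals", {
  g <- small_genome()
  pm <- small_partition()
  sim <- simulate_population_variants(g, small_config(), seed = 4)
  ## suppress the small-count chi-square approximation notice
  dens <- suppressWarnings(density_by_class(sim$variants, pm, g))
  tab <- dens$table
  expect_equal(tab$sites[tab$class == "Intergenic"],
               unname(pm$totals["intergenic"]))
  expect_equal(tab$sites[tab$class == "Synonymous"], pm$syn_sites)
  ## per-class counts equal a direct tally of the truth records
  truth <- sim$truth
  expect_equal(tab$snps[tab$class == "Intergenic"],
               sum(truth$class == "intergenic" & truth$vclass == "SNP"))
  expect_equal(tab$snps[tab$class == "Protein Coding"],
               sum(truth$class == "CDS" & truth$vclass == "SNP"))
  expect_equal(tab$indels[tab$class == "Intron"],
               sum(truth$class == "intron" & truth$vclass == "indel"))
  ## row sums: total row equals the sum over classes (without the syn/nonsyn
  ## double count)
  expect_equal(tab$snps[tab$class == "Total"], sum(truth$vclass == "SNP"))
  ## no variants -> all densities zero
  vs0 <- make_vs(integer(), character(), character(),
                 GT = matrix(NA_integer_, 0, 2))
  d0 <- suppressWarnings(density_by_class(vs0, pm, g))
  expect_true(all(d0$table$snps == 0))
  expect_error(density_by_class(make_vs(g$length + 50, "A", "G",
                                        GT = matrix(1L, 1, 1)), pm, g),
               "not covered")
})

test_that("per-class densities stay inside binomial bounds of configured rates", {
  g <- small_genome()
  pm <- small_partition()
  cfg <- small_config()
  counts <- sapply(1:25, function(s) {
    tr <- simulate_population_variants(g, cfg, seed = 400 + s, partition = pm)$truth
    sum(tr$class == "intergenic" & tr$vclass == "SNP")
  })
  n_sites <- unname(pm$totals["intergenic"])
  rate <- cfg$snp_rate[["intergenic"]]
  ## pooled count over 25 seeds against the binomial 95% interval
  total <- sum(counts)
  expect_gt(total, qbinom(0.025, 25 * n_sites, rate) - 1)
  expect_lt(total, qbinom(0.975, 25 * n_sites, rate) + 1)
})

test_that("unique-line screen keeps only single-line variants", {
  samples <- sprintf("s%d", 1:6)
  line_map <- setNames(rep(c("L1", "L2", "L3"), each = 2), samples)
  gt <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L),    # L1 only
              c(1L, 0L, 1L, 0L, 0L, 0L),    # L1 + L2: excluded
              c(0L, 0L, 0L, 0L, 1L, 0L))    # one replicate of L3
  vs <- variant_set(c(5, 9, 11), rep("A", 3), rep("G", 3),
                    GT = gt, DP = matrix(100L, 3, 6),
                    AD_ALT = matrix(15L, 3, 6), samples = samples)
  u <- unique_line_variants(vs, line_map)
  expect_identical(u$pos0, c(5L, 11L))
  expect_identical(u$line, c("L1", "L3"))
  expect_equal(u$max_fraction, c(0.15, 0.15))
  expect_error(unique_line_variants(vs, line_map[-1]), "unmapped")
  ## brute-force comparison on a random assignment
  set.seed(12)
  gt2 <- matrix(rbinom(60, 1, 0.2), 10, 6)
  vs2 <- variant_set(1:10, rep("A", 10), rep("G", 10), GT = gt2,
                     DP = matrix(100L, 10, 6), samples = samples)
  u2 <- unique_line_variants(vs2, line_map)
  oracle <- which(apply(gt2, 1, function(r)
    sum(r) > 0 && length(unique(line_map[samples[r == 1]])) == 1))
  expect_identical(u2$site, oracle)
})

test_that("heteroplasmy screen uses an inclusive fraction floor below fixation", {
  dp <- matrix(100L, 3, 2)
  ad <- rbind(c(5L, 0L), c(10L, 0L), c(100L, 12L))
  vs <- variant_set(c(3, 6, 9), rep("A", 3), rep("C", 3),
                    GT = matrix(1L, 3, 2), DP = dp, AD_ALT = ad,
                    samples = c("x", "y"))
  h <- heteroplasmic_candidates(vs)
  ## 0.05 not flagged; 0.10 flagged (boundary); 1.0 not (fixed), 0.12 flagged
  expect_identical(h$pos0, c(6L, 9L))
  expect_identical(h$sample, c("x", "y"))
})

test_that("simulated 15% heteroplasmy at 100x depth is detected at the binomial rate", {
  ## detection requires >= 10 alt reads of 100; the exact binomial truth
  p_detect <- 1 - pbinom(9, 100, 0.15)
  set.seed(77)
  hits <- 0L
  for (i in 1:200) {
    ad <- rbinom(1, 100, 0.15)
    vs <- variant_set(1, "A", "G", GT = matrix(1L, 1, 1),
                      DP = matrix(100L, 1, 1), AD_ALT = matrix(ad, 1, 1))
    hits <- hits + (nrow(heteroplasmic_candidates(vs)) == 1L)
  }
  ## observed detection rate within the binomial 95% interval of the truth
  expect_gte(hits, qbinom(0.025, 200, p_detect))
  expect_lte(hits, qbinom(0.975, 200, p_detect))
  expect_gte(hits / 200, 0.90)
})
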