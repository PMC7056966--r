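# Shared fixtures: one small toy genome reused across test files (built
# once per test run; everything derived from it is seeded).

small_config <- function(...) {
  sim_config(genome_length = 12000L, n_mtpt = 1L, n_repeats = 1L,
             n_homopolymers = 8L, ...)
}

.fixture_env <- new.env()

small_genome <- function() {
  if (is.null(.fixture_env$genome))
    .fixture_env$genome <- build_toy_genome(small_config(), seed = 101)
  .fixture_env$genome
}

small_partition <- function() {
  if (is.null(.fixture_env$partition))
    .fixture_env$partition <- partition_positions(small_genome())
  .fixture_env$partition
}

random_dna_fixture <- function(n, seed = 5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# simulated reads all carry simple <n>M cigars
cigar_width_fixture <- function(cigar) as.integer(sub("M", "", cigar))

# balanced 2-treatment x 3-line x 3-replicate design labels
ma_labels <- function() {
  trt <- rep(c("control", "salt"), each = 9)
  line <- paste0(substr(trt, 1, 1), rep(rep(1:3, each = 3), 2))
  list(treatment = trt, line = line)
}
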