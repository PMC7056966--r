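## Paired-read simulation with per-window copy-number structure and
## repeat-mediated recombinant conformations, the full MA-line design, and
## ddPCR droplets.  Alignment records are emitted directly (coordinates,
## flags, mate fields and insert sizes), so the pipeline can be exercised
## without an external aligner; a FASTQ export is available for users who
## want to run one.

#' Simulate paired-read alignments over a genome
#'
#' Fragment start positions are drawn with per-window sampling weights
#' proportional to `multipliers`; fragment lengths are normal
#' (`insert_mean`, `insert_sd`), truncated at the read length.  For each
#' in-range direct repeat pair carrying a nonzero recombinant fraction, a
#' fragment fully spanning one repeat copy is re-drawn from the recombined
#' conformation with that probability, and its distal mate is mapped back to
#' the flank of the other copy — exactly the geometry
#' [classify_read_pair()] detects.  Fragments are constrained within the
#' linear map (no origin wrap-around), consistent with excluding the edge
#' windows downstream.
#'
#' @param genome `annotated_genome`.
#' @param config [sim_config()] (read model, window size, depth).
#' @param seed integer seed.
#' @param multipliers per-window relative copy number (recycled to the
#'   number of windows); default flat.
#' @param recombinant_fractions numeric vector, one per row of
#'   `genome$repeats` (default `config$recombinant_fraction` for in-range
#'   direct repeats).
#' @param sample_name prefix for read names.
#' @param depth target mean depth (default `config$depth`).
#' @param dup_rate fraction of fragments duplicated and flagged as
#'   duplicates (default 0).
#' @return alignment data.frame (two records per fragment) plus a `truth`
#'   attribute with the realised multipliers and recombinant counts.
#' @export
simulate_reads <- function(genome, config = sim_config(), seed = 1L,
                           multipliers = NULL, recombinant_fractions = NULL,
                           sample_name = "sim", depth = NULL, dup_rate = 0) {
  local_seed(seed, {
    L <- genome$length
    rl <- config$read_length
    if (is.null(depth)) depth <- config$depth
    if (depth <= 0) return(empty_alignments())
    if (config$insert_mean < rl) stop("insert mean shorter than read length")
    win <- tile_windows(L, config$window_size)
    n_win <- nrow(win)
    if (is.null(multipliers)) multipliers <- 1
    multipliers <- rep_len(multipliers, n_win)
    reps <- genome$repeats
    if (!is.null(reps) && nrow(reps)) {
      use <- reps$orientation == "direct" & (reps$in_range %||% TRUE)
      if (is.null(recombinant_fractions))
        recombinant_fractions <- ifelse(use, config$recombinant_fraction, 0)
      recombinant_fractions <- rep_len(recombinant_fractions, nrow(reps)) *
        as.numeric(use)
    } else recombinant_fractions <- numeric(0)

    n_frag <- round(depth * L / (2 * rl))
    ## per-position start weight = multiplier of the containing window
    w_pos <- multipliers[pmin(n_win, (seq_len(L) - 1L) %/% config$window_size + 1L)]
    ins <- pmax(rl, round(rnorm(n_frag, config$insert_mean, config$insert_sd)))
    start <- sample.int(L, n_frag, replace = TRUE, prob = w_pos) - 1L
    keep <- start + ins <= L
    start <- start[keep]; ins <- ins[keep]
    n_frag <- length(start)

    ## conformation assignment per fragment
    junction <- rep(0L, n_frag)      # 0 = reference, j>0 = repeat row (AB), -j = BA
    n_recomb <- integer(length(recombinant_fractions))
    if (length(recombinant_fractions)) for (j in seq_len(nrow(reps))) {
      f <- recombinant_fractions[j]
      if (f <= 0) next
      spans1 <- start < reps$copy1_start[j] & start + ins > reps$copy1_end[j]
      spans2 <- start < reps$copy2_start[j] & start + ins > reps$copy2_end[j]
      cand <- which((spans1 | spans2) & junction == 0L)
      conv <- cand[runif(length(cand)) < f]
      junction[conv] <- ifelse(spans1[conv], j, -j)
      n_recomb[j] <- length(conv)
    }

    pos1 <- start
    pos2 <- start + ins - rl          # leftmost position of the reverse mate
    discord <- junction != 0L
    for (i in which(discord)) {
      j <- abs(junction[i])
      if (junction[i] > 0L) {
        ## AB: molecule = ref[0:copy1_end) + ref[copy2_end:); the reverse
        ## mate maps shifted right by the excised distance
        shift <- reps$copy2_end[j] - reps$copy1_end[j]
        p2 <- pos2[i] + shift
      } else {
        ## BA: molecule = ref[0:copy2_end) + ref[copy1_end:); shifted left
        shift <- reps$copy2_end[j] - reps$copy1_end[j]
        p2 <- pos2[i] - shift
      }
      if (p2 < 0 || p2 + rl > L) { junction[i] <- 0L; next }
      pos2[i] <- p2
    }
    tlen <- pos2 + rl - pos1
    qname <- sprintf("%s_f%06d", sample_name, seq_len(n_frag))
    f1 <- ifelse(junction != 0L, 97L, 99L)     # paired, mate reverse, first
    f2 <- ifelse(junction != 0L, 145L, 147L)   # paired, reverse, second
    aln <- data.frame(
      qname = rep(qname, 2L),
      flag = c(f1, f2),
      pos = c(pos1, pos2),
      mapq = 60L,
      cigar = sprintf("%dM", rl),
      mpos = c(pos2, pos1),
      tlen = c(tlen, -tlen),
      seq = NA_character_,
      stringsAsFactors = FALSE)
    if (dup_rate > 0 && n_frag > 0) {
      d <- which(runif(n_frag) < dup_rate)
      if (length(d)) {
        dup <- aln[c(d, d + n_frag), , drop = FALSE]
        dup$flag <- dup$flag + 1024L
        dup$qname <- paste0(dup$qname, "_dup")
        aln <- rbind(aln, dup)
      }
    }
    aln <- aln[order(aln$pos), ]
    rownames(aln) <- NULL
    attr(aln, "truth") <- list(multipliers = multipliers,
                               recombinant_fractions = recombinant_fractions,
                               n_recombinant_fragments = n_recomb,
                               n_fragments = n_frag, seed = seed)
    aln
  })
}

empty_alignments <- function() {
  data.frame(qname = character(), flag = integer(), pos = integer(),
             mapq = integer(), cigar = character(), mpos = integer(),
             tlen = integer(), seq = character())
}

#' Export simulated alignments as FASTQ mate files
#'
#' @param alignments alignment data.frame from [simulate_reads()].
#' @param genome `annotated_genome` providing the reference sequence.
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @export
write_fastq_pair <- function(alignments, genome, prefix) {
  a <- alignments
  a$rlen <- cigar_ref_width(a$cigar)
  get_seq <- function(rows, rc) {
    vapply(seq_len(nrow(rows)), function(i) {
      s <- substr(genome$sequence, rows$pos[i] + 1L, rows$pos[i] + rows$rlen[i])
      if (rc[i]) revcomp(s) else s
    }, character(1))
  }
  for (mate in 1:2) {
    rows <- a[flag_has(a$flag, if (mate == 1) FLAG_READ1 else FLAG_READ2), ]
    rc <- flag_has(rows$flag, FLAG_REVERSE)
    seqs <- get_seq(rows, rc)
    out <- file(sprintf("%s_%d.fastq", prefix, mate), "w")
    writeLines(paste0("@", rows$qname, "/", mate, "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), out)
    close(out)
  }
  invisible(prefix)
}

## shared layout of the MA design: sample sheet, smooth baseline profile,
## shifted window block and per-sample window multipliers
ma_design_layout <- function(config, seed, n_win) {
  seeds <- derive_seeds(seed, 2L)
  base <- local_seed(seeds[1], {
    ## smooth baseline: circular moving-average of log-scale noise
    raw <- rnorm(n_win, 0, config$baseline_amplitude)
    k <- config$baseline_scale
    baseline <- exp(stats::filter(c(raw, raw[seq_len(k)]), rep(1 / k, k),
                                  sides = 1)[k + seq_len(n_win) - 1L] * sqrt(k))
    shift_start <- sample(max(1L, n_win - config$n_shifted_windows - 2L), 1) + 1L
    list(baseline = baseline,
         shifted = if (config$n_shifted_windows > 0)
           shift_start + seq_len(config$n_shifted_windows) - 1L else integer(0))
  })
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         line_i = seq_len(config$n_lines_per_treatment),
                         treatment = c("control", "salt"),
                         stringsAsFactors = FALSE)
  samples$line <- sprintf("%s_L%d", substr(samples$treatment, 1, 1), samples$line_i)
  samples$sample <- sprintf("%s_r%d", samples$line, samples$replicate)
  line_ids <- unique(samples$line)
  line_noise <- local_seed(seeds[2], {
    m <- vapply(line_ids, function(l)
      exp(rnorm(n_win, 0, config$line_sd)), numeric(n_win))
    colnames(m) <- line_ids
    m
  })
  multipliers <- lapply(seq_len(nrow(samples)), function(i) {
    mult <- base$baseline * line_noise[, samples$line[i]]
    if (samples$treatment[i] == "salt")
      mult[base$shifted] <- mult[base$shifted] * config$shift
    mult
  })
  names(multipliers) <- samples$sample
  list(samples = samples, baseline = base$baseline, shifted = base$shifted,
       multipliers = multipliers)
}

#' Simulate a mutation-accumulation design at the window level
#'
#' Generates the per-sample window CPMM matrix directly, without read
#' simulation: the same design layout as [simulate_ma_design()] (smooth
#' baseline, treatment-shifted window block, line-level noise), with window
#' sampling noise matched to the read model — the coefficient of variation
#' of a window mean at depth d is `1/sqrt(d (window + insert) / (2
#' read_length))` — and per-sample per-million renormalisation.  Useful for
#' many-seed power and calibration studies where full read simulation is
#' unnecessary.
#'
#' @param config [sim_config()].
#' @param seed integer seed.
#' @param n_windows number of windows (default: genome length / window
#'   size).
#' @return `window_matrix` with a `truth` attribute (baseline, shifted
#'   windows, per-sample multipliers).
#' @export
simulate_window_profiles <- function(config = sim_config(), seed = 1L,
                                     n_windows = NULL) {
  seeds <- derive_seeds(seed, 2L)
  if (is.null(n_windows))
    n_windows <- config$genome_length %/% config$window_size
  layout <- ma_design_layout(config, seeds[1], n_windows)
  samples <- layout$samples
  n_eff <- config$depth * (config$window_size + config$insert_mean) /
    (2 * config$read_length)
  cv <- 1 / sqrt(n_eff)
  wm <- local_seed(seeds[2], {
    gc <- runif(n_windows, 0.35, 0.55)
    hp <- rpois(n_windows, 1)
    cpmm <- t(vapply(seq_len(nrow(samples)), function(i) {
      mu <- layout$multipliers[[i]] * (1 + config$gc_effect * (gc - 0.45))
      x <- mu * (1 + rnorm(n_windows, 0, cv))
      x <- pmax(x, 0.01 * mean(x))
      x / mean(x) * 1e6 / n_windows     # per-million renormalisation
    }, numeric(n_windows)))
    rownames(cpmm) <- samples$sample
    win <- tile_windows(n_windows * config$window_size, config$window_size)
    win$gc <- gc; win$homopolymers <- hp
    win$excluded <- c(TRUE, rep(FALSE, n_windows - 2L), TRUE)
    win$reason <- ifelse(win$excluded, "edge", "")
    structure(list(windows = win, cpmm = cpmm, samples = samples$sample),
              class = "window_matrix")
  })
  attr(wm, "truth") <- list(baseline = layout$baseline,
                            shifted = layout$shifted,
                            multipliers = layout$multipliers,
                            samples = samples, seed = seed)
  wm
}

#' Simulate the full mutation-accumulation design
#'
#' Two treatments (control, salt) x `n_lines_per_treatment` lines x
#' `n_replicates` replicates.  All samples share a smooth baseline
#' copy-number profile (an autocorrelated log-scale curve, emulating the
#' heterogeneous, regionally coherent coverage of real mitogenome
#' libraries); a contiguous block of `n_shifted_windows` windows is
#' multiplied by `shift` in the salt treatment; each line adds small
#' window-level log-normal noise (`line_sd`); replicates differ by read
#' sampling.  Per-line unique heteroplasmic variants are planted at
#' `heteroplasmy_fraction`.
#'
#' @param config [sim_config()].
#' @param seed integer seed.
#' @param genome optional pre-built genome (built from `config` otherwise).
#' @return list with `genome`, `alignments` (named list per sample),
#'   `samples` (data.frame: sample, treatment, line, replicate), `variants`
#'   (a `variant_set` holding planted heteroplasmies), and `truth` (baseline
#'   profile, shifted windows, per-sample multipliers, recombinant
#'   fractions, heteroplasmy records).
#' @export
simulate_ma_design <- function(config = sim_config(), seed = 1L, genome = NULL) {
  seeds <- derive_seeds(seed, 6L)
  if (is.null(genome)) genome <- build_toy_genome(config, seeds[1])
  L <- genome$length
  n_win <- nrow(tile_windows(L, config$window_size))
  layout <- ma_design_layout(config, seeds[2], n_win)
  samples <- layout$samples
  read_seeds <- derive_seeds(seeds[4], nrow(samples))
  alignments <- list()
  for (i in seq_len(nrow(samples))) {
    aln <- simulate_reads(genome, config, seed = read_seeds[i],
                          multipliers = layout$multipliers[[samples$sample[i]]],
                          sample_name = samples$sample[i])
    alignments[[samples$sample[i]]] <- aln
  }
  line_ids <- unique(samples$line)
  baseline <- layout$baseline; shifted <- layout$shifted
  mult_truth <- layout$multipliers
  ## planted per-line unique heteroplasmies
  variants <- if (config$n_heteroplasmies <= 0) NULL else local_seed(seeds[5], {
    n_het <- config$n_heteroplasmies * length(line_ids)
    pos <- sort(sample(L - 2L, n_het))
    base <- substring(genome$sequence, pos + 1L, pos + 1L)
    alt <- vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1))
    owner <- rep(line_ids, each = config$n_heteroplasmies)
    DP <- matrix(rpois(n_het * nrow(samples), config$coverage_mean),
                 n_het, nrow(samples))
    AD <- matrix(0L, n_het, nrow(samples))
    for (v in seq_len(n_het)) {
      carriers <- which(samples$line == owner[v])
      AD[v, carriers] <- rbinom(length(carriers), DP[v, carriers],
                                config$heteroplasmy_fraction)
    }
    GT <- ifelse(AD > 0, 1L, 0L)
    vset <- variant_set(pos, base, alt, vclass = rep("SNP", n_het),
                        GT = GT, DP = DP, AD_ALT = AD,
                        samples = samples$sample)
    attr(vset, "owner_line") <- owner
    vset
  })
  list(genome = genome, alignments = alignments,
       samples = samples[, c("sample", "treatment", "line", "replicate")],
       variants = variants,
       truth = list(baseline = baseline, shifted_windows = shifted,
                    shift = config$shift, multipliers = mult_truth,
                    recombinant_fraction = config$recombinant_fraction,
                    heteroplasmy_fraction = config$heteroplasmy_fraction,
                    seed = seed))
}

#' Simulate ddPCR droplet counts
#'
#' Each droplet is positive with probability `1 - exp(-copies x volume)`,
#' the Poisson zero-class complement.
#'
#' @param copies_per_ul true template concentration.
#' @param droplet_volume_ul droplet volume in microlitres.
#' @param n_droplets number of droplets.
#' @param seed integer seed.
#' @return list with `n_positive`, `n_total`.
#' @export
simulate_ddpcr <- function(copies_per_ul, droplet_volume_ul = 0.00085,
                           n_droplets = 20000L, seed = 1L) {
  stopifnot(copies_per_ul >= 0, droplet_volume_ul > 0, n_droplets > 0)
  local_seed(seed, {
    p <- 1 - exp(-copies_per_ul * droplet_volume_ul)
    list(n_positive = rbinom(1, n_droplets, p), n_total = as.integer(n_droplets))
  })
}
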