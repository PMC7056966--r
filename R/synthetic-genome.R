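## Seeded generator of toy annotated mitogenomes.  The defaults emulate the
## composition of the A. thaliana reference mitogenome at 50-kb scale:
## ~8.5% protein-coding, 1.4% rRNA, 0.5% tRNA, 0.3% pseudogene, 9.6% intron
## and ~80% intergenic sequence, ~45% GC, with planted intermediate-size
## repeat pairs, plastid-derived (mtpt) intervals and long homopolymers.

#' Simulation configuration
#'
#' Central collection of generator parameters with defaults emulating the
#' study conditions: functional-class proportions scaled from the reference
#' mitogenome, strongly AT-biased substitution spectrum (gain:loss = 7),
#' per-class SNP/indel densities matching the observed population tables,
#' 2x150 bp paired reads with a 245-bp mean insert, a 2-treatment x
#' 3-line x 3-replicate mutation-accumulation design with up to ~20% window
#' shifts, and 20,000-droplet ddPCR.
#'
#' @param ... overrides of any default listed below.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    genome_length = 50000L,
    gc = 0.45,
    ## class proportions (protein-coding incl. terminal stops, then rRNA,
    ## tRNA, pseudogene, intron; remainder intergenic)
    prop_cds = 0.085, prop_rrna = 0.0142, prop_trna = 0.0046,
    prop_pseudo = 0.0034, prop_intron = 0.096,
    cds_gene_bp = 900L, rrna_bp = 1500L, trna_bp = 75L, pseudo_bp = 300L,
    intron_bp = 1000L,
    n_homopolymers = 30L, homopolymer_len = c(8L, 12L),
    n_mtpt = 2L, mtpt_bp = 1000L,
    ## planted repeat pairs (direct), length/identity within the scan range;
    ## short enough that the default insert model can span a copy
    n_repeats = 2L, repeat_bp = 150L, repeat_identity = 0.85,
    ## population variants
    n_accessions = 24L,
    snp_rate = c(CDS = 0.0013, rRNA = 0.0006, tRNA = 0.0000,
                 pseudogene = 0.0040, intron = 0.0020, intergenic = 0.0034),
    indel_rate = c(CDS = 0, rRNA = 0, tRNA = 0, pseudogene = 0,
                   intron = 0.0005, intergenic = 0.0006),
    at_bias = 7, ts_fraction = 0.4, p_gain_gc = 0.9,
    outgroup_divergence = 0.05, outgroup_indel_rate = 0.002,
    ## MA design
    n_lines_per_treatment = 3L, n_replicates = 3L,
    baseline_amplitude = 0.15, baseline_scale = 10L,
    line_sd = 0.01,
    ## ~6% of windows shifted, mirroring the sparse treatment effects seen
    ## in real windowed scans; shift magnitude within the observed range
    n_shifted_windows = 6L, shift = 1.15,
    n_heteroplasmies = 2L, heteroplasmy_fraction = 0.15,
    recombinant_fraction = 0.05,
    ## read model (2x150, insert 245 +/- 50); mitochondrial enrichment makes
    ## deep mitogenome coverage the norm, hence the 500x default
    read_length = 150L, insert_mean = 245, insert_sd = 50, depth = 500,
    coverage_mean = 100,
    gc_effect = 0,
    window_size = 500L,
    ## ddPCR
    ddpcr_copies_per_ul = 1000, ddpcr_droplet_volume_ul = 0.00085,
    ddpcr_n_droplets = 20000L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## random in-frame coding sequence: ATG + random sense codons + stop
random_cds <- function(n_bp, gc = 0.45) {
  stopifnot(n_bp %% 3 == 0, n_bp >= 9)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  ## weight codons toward the target GC
  w <- vapply(sense, function(cd) {
    g <- sum(strsplit(cd, "")[[1]] %in% c("G", "C"))
    (gc / (1 - gc))^(g - 1.5)
  }, numeric(1))
  stops <- names(code)[code == "*"]
  body <- sample(sense, n_bp / 3 - 2, replace = TRUE, prob = w)
  paste(c("ATG", body, sample(stops, 1)), collapse = "")
}

#' Build a toy annotated circular mitogenome
#'
#' Lays out protein-coding genes (some on the minus strand, some split by an
#' intron), rRNA, tRNA and pseudogene features around a circle separated by
#' intergenic gaps sized to meet the configured class proportions, then
#' plants direct repeat pairs, mtpt intervals and long homopolymer runs in
#' the largest intergenic gaps.  Deterministic for a given (config, seed).
#'
#' @param config [sim_config()].
#' @param seed integer seed.
#' @return `annotated_genome` with an attached `truth` attribute recording
#'   planted element coordinates.
#' @export
build_toy_genome <- function(config = sim_config(), seed = 1L) {
  local_seed(seed, {
    L <- config$genome_length
    ## feature blocks to place
    blocks <- list()
    add <- function(kind, bp, gene) blocks[[length(blocks) + 1L]] <<-
      list(kind = kind, bp = as.integer(bp), gene = gene)
    cds_bp <- round(config$prop_cds * L)
    n_genes <- max(1L, round(cds_bp / config$cds_gene_bp))
    per_gene <- as.integer(cds_bp / n_genes) %/% 3L * 3L
    n_introns <- min(n_genes, max(0L, round(config$prop_intron * L / config$intron_bp)))
    intron_each <- if (n_introns > 0) round(config$prop_intron * L / n_introns) else 0L
    intron_genes <- sample(n_genes, n_introns)
    for (g in seq_len(n_genes))
      add(if (g %in% intron_genes) "CDS_split" else "CDS", per_gene,
          sprintf("gene%02d", g))
    ## unit counts adapt so small classes are never rounded away
    add_class <- function(kind, prop, unit, stem) {
      bp <- round(prop * L)
      if (bp <= 0) return()
      n <- max(1L, round(bp / unit))
      for (i in seq_len(n)) add(kind, round(bp / n), sprintf("%s%02d", stem, i))
    }
    add_class("rRNA", config$prop_rrna, config$rrna_bp, "rrn")
    add_class("tRNA", config$prop_trna, config$trna_bp, "trn")
    add_class("pseudogene", config$prop_pseudo, config$pseudo_bp, "psi")
    blocks <- blocks[sample(length(blocks))]
    total_feat <- sum(vapply(blocks, function(b)
      b$bp + if (b$kind == "CDS_split") intron_each else 0L, numeric(1)))
    n_gaps <- length(blocks) + 1L
    gap_total <- L - total_feat
    if (gap_total < n_gaps * 100L) stop("infeasible proportions: no room for intergenic gaps")
    ## random gap sizes, minimum 100 bp each
    gw <- as.vector(stats::rmultinom(1, gap_total - n_gaps * 100L,
                                     prob = runif(n_gaps) + 0.5)) + 100L
    seqs <- character(0)
    feats <- list()
    pos <- 0L
    emit <- function(s) { seqs <<- c(seqs, s); pos <<- pos + nchar(s) }
    feat <- function(kind, start, end, strand, gene, phase = 0L)
      feats[[length(feats) + 1L]] <<- data.frame(kind = kind, start = start,
                                                 end = end, strand = strand,
                                                 gene = gene, phase = phase)
    gaps <- list()  # intergenic intervals, for planting
    for (i in seq_along(blocks)) {
      gaps[[i]] <- c(pos, pos + gw[i])
      emit(random_dna(gw[i], config$gc))
      b <- blocks[[i]]
      strand <- sample(c("+", "-"), 1)
      if (b$kind == "CDS") {
        cds <- random_cds(b$bp, config$gc)
        emit(if (strand == "+") cds else revcomp(cds))
        feat("CDS", pos - b$bp, pos, strand, b$gene)
      } else if (b$kind == "CDS_split") {
        cds <- random_cds(b$bp, config$gc)
        cut <- (sample(b$bp %/% 6L, 1) * 3L)  # split point in frame
        ex1 <- substr(cds, 1, cut); ex2 <- substr(cds, cut + 1L, b$bp)
        if (strand == "+") {
          emit(ex1); feat("CDS", pos - nchar(ex1), pos, "+", b$gene)
          emit(random_dna(intron_each, config$gc))
          feat("intron", pos - intron_each, pos, "+", b$gene)
          emit(ex2); feat("CDS", pos - nchar(ex2), pos, "+", b$gene,
                          phase = (3L - cut %% 3L) %% 3L)
        } else {
          ## minus strand: exon2 sits leftmost on the genome; annotation
          ## order (coding order) still ex1 then ex2
          emit(revcomp(ex2))
          ex2_iv <- c(pos - nchar(ex2), pos)
          emit(random_dna(intron_each, config$gc))
          intron_iv <- c(pos - intron_each, pos)
          emit(revcomp(ex1))
          feat("CDS", pos - nchar(ex1), pos, "-", b$gene)
          feat("intron", intron_iv[1], intron_iv[2], "-", b$gene)
          feat("CDS", ex2_iv[1], ex2_iv[2], "-", b$gene,
               phase = (3L - cut %% 3L) %% 3L)
        }
      } else {
        emit(random_dna(b$bp, config$gc))
        feat(b$kind, pos - b$bp, pos, strand, b$gene)
      }
    }
    gaps[[n_gaps]] <- c(pos, pos + gw[n_gaps])
    emit(random_dna(gw[n_gaps], config$gc))
    sequence <- paste(seqs, collapse = "")
    stopifnot(nchar(sequence) == L)
    features <- do.call(rbind, feats)

    ## plant repeats, mtpt and homopolymers in the largest gaps
    gap_df <- do.call(rbind, lapply(gaps, function(g)
      data.frame(start = g[1], end = g[2])))
    gap_df$width <- gap_df$end - gap_df$start
    gap_df <- gap_df[order(-gap_df$width), ]
    take <- 1L
    next_gap <- function(min_bp) {
      while (take <= nrow(gap_df) && gap_df$width[take] < min_bp + 40L)
        take <<- take + 1L
      if (take > nrow(gap_df)) stop("infeasible proportions: gaps too small for planted elements")
      g <- gap_df[take, ]; take <<- take + 1L
      g
    }
    plant <- function(at, s) {
      substr(sequence, at + 1L, at + nchar(s)) <<- s
    }
    repeats <- empty_repeat_pairs()
    if (config$n_repeats > 0) for (r in seq_len(config$n_repeats)) {
      unit <- random_dna(config$repeat_bp, config$gc)
      mut <- mutate_sequence(unit, 1 - config$repeat_identity)
      g1 <- next_gap(config$repeat_bp); g2 <- next_gap(config$repeat_bp)
      at1 <- g1$start + 20L; at2 <- g2$start + 20L
      plant(at1, unit); plant(at2, mut)
      lo <- min(at1, at2); hi <- max(at1, at2)
      repeats <- rbind(repeats, data.frame(
        copy1_start = lo, copy1_end = lo + config$repeat_bp,
        copy2_start = hi, copy2_end = hi + config$repeat_bp,
        orientation = "direct", length = config$repeat_bp,
        identity = config$repeat_identity, in_range = TRUE))
    }
    mtpt <- data.frame(start = integer(), end = integer())
    if (config$n_mtpt > 0) for (m in seq_len(config$n_mtpt)) {
      g <- next_gap(config$mtpt_bp)
      at <- g$start + 20L
      mtpt <- rbind(mtpt, data.frame(start = at, end = at + config$mtpt_bp))
    }
    hp_truth <- integer(0)
    rem <- if (take <= nrow(gap_df)) gap_df[take:nrow(gap_df), , drop = FALSE]
           else gap_df[0, , drop = FALSE]
    rem <- rem[rem$width > 60L, , drop = FALSE]
    if (config$n_homopolymers > 0 && nrow(rem) > 0) {
      ## spread homopolymers over remaining gaps
      for (h in seq_len(config$n_homopolymers)) {
        g <- rem[1L + (h - 1L) %% nrow(rem), ]
        len <- sample(config$homopolymer_len[1]:config$homopolymer_len[2], 1)
        at <- g$start + 10L + ((h - 1L) %/% nrow(rem)) * 25L
        if (at + len + 2L >= g$end) next
        base <- sample(c("A", "T", "G", "C"), 1, prob = c(.4, .4, .1, .1))
        other <- setdiff(c("A", "C", "G", "T"), base)
        ## break up the run so it doesn't merge with neighbours
        plant(at, paste0(sample(other, 1), strrep(base, len), sample(other, 1)))
        hp_truth <- c(hp_truth, at + 1L)
      }
    }
    g <- annotated_genome(sequence, features, mtpt = mtpt, repeats = repeats)
    attr(g, "truth") <- list(repeats = repeats, mtpt = mtpt,
                             homopolymer_starts = hp_truth, seed = seed)
    g
  })
}

## point-mutate a sequence at the given per-base rate (no indels)
mutate_sequence <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
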