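## Simulated population variation: SNPs placed per functional class at
## configured densities, derived alleles drawn from an AT-biased directional
## spectrum, derived-allele counts from a neutral site-frequency spectrum,
## indels confined to introns and intergenic sequence, and a diverged
## outgroup with true gapped alignment blocks for polarization.

## draw a derived allele for an ancestral base under the configured spectrum:
## at G/C sites a change is AT-gaining with probability p_gain_gc (transition
## vs transversion split by ts_fraction), otherwise the neutral G<->C flip;
## at A/T sites the losing probability is solved so that the *overall*
## expected gain:loss ratio equals at_bias given the composition of the
## sampled sites.
derive_allele <- function(anc, p_gain, p_loss, ts_fraction) {
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  flip <- c(A = "T", T = "A", G = "C", C = "G")
  if (anc %in% c("G", "C")) {
    if (runif(1) < p_gain) {
      if (runif(1) < ts_fraction) ts_of[[anc]]          # G->A / C->T
      else setdiff(c("A", "T"), ts_of[[anc]])           # G->T / C->A
    } else flip[[anc]]
  } else {
    if (runif(1) < p_loss) {
      if (runif(1) < ts_fraction) ts_of[[anc]]          # A->G / T->C
      else setdiff(c("G", "C"), ts_of[[anc]])           # A->C / T->G
    } else flip[[anc]]
  }
}

#' Simulate population variants over a toy genome
#'
#' SNP counts per functional class are binomial at the configured per-site
#' rates; derived alleles follow a directional spectrum whose expected
#' AT-gaining:AT-losing ratio equals `config$at_bias`; derived-allele counts
#' across accessions follow a neutral 1/k site-frequency spectrum (so the
#' derived allele is usually, but not always, the minor allele); indels
#' (1-bp deletions) are placed only where their class rate is nonzero —
#' introns and intergenic sequence under the defaults.  The reference allele
#' is the ancestral state throughout.
#'
#' @param genome `annotated_genome` from [build_toy_genome()].
#' @param config [sim_config()].
#' @param seed integer seed.
#' @param partition optional precomputed partition.
#' @return list with `variants` (a `variant_set` across
#'   `config$n_accessions` samples) and `truth` (data.frame: `pos0`,
#'   `class`, `ancestral`, `derived`, `carriers`, `vclass`).
#' @export
simulate_population_variants <- function(genome, config = sim_config(), seed = 1L,
                                         partition = NULL) {
  local_seed(seed, {
    if (is.null(partition)) partition <- partition_positions(genome)
    cls <- as.character(partition$class)
    cls[cls == "CDS"] <- "CDS"
    n_acc <- config$n_accessions
    base_at <- strsplit(genome$sequence, "")[[1]]

    pick_sites <- function(rates) {
      out <- integer(0)
      for (cl in names(rates)) {
        pool <- which(cls == cl)
        if (!length(pool) || rates[[cl]] <= 0) next
        n <- rbinom(1, length(pool), rates[[cl]])
        if (n > 0) out <- c(out, sample(pool, min(n, length(pool))))
      }
      sort(out)
    }
    snp_pos <- pick_sites(config$snp_rate)
    indel_pos <- pick_sites(config$indel_rate)
    indel_pos <- setdiff(indel_pos, c(snp_pos, snp_pos - 1L, genome$length))

    ## AT-loss probability solved so E[gain]/E[loss] = at_bias for the
    ## realised site composition
    anc_snp <- base_at[snp_pos]
    f_gc <- mean(anc_snp %in% c("G", "C"))
    p_loss <- min(1, f_gc * config$p_gain_gc / (max(1e-9, 1 - f_gc) * config$at_bias))

    rows <- list(); GT <- list()
    for (i in seq_along(snp_pos)) {
      anc <- anc_snp[i]
      der <- derive_allele(anc, config$p_gain_gc, p_loss, config$ts_fraction)
      k <- sample(seq_len(n_acc - 1L), 1, prob = 1 / seq_len(n_acc - 1L))
      carriers <- sample(n_acc, k)
      g <- integer(n_acc); g[carriers] <- 1L
      rows[[length(rows) + 1L]] <- data.frame(
        pos0 = snp_pos[i] - 1L, class = cls[snp_pos[i]], ancestral = anc,
        derived = der, carriers = k, vclass = "SNP", stringsAsFactors = FALSE)
      GT[[length(GT) + 1L]] <- g
    }
    for (p in indel_pos) {
      k <- sample(seq_len(n_acc - 1L), 1, prob = 1 / seq_len(n_acc - 1L))
      carriers <- sample(n_acc, k)
      g <- integer(n_acc); g[carriers] <- 1L
      rows[[length(rows) + 1L]] <- data.frame(
        pos0 = p - 1L, class = cls[p], ancestral = NA_character_,
        derived = NA_character_, carriers = k, vclass = "indel",
        stringsAsFactors = FALSE)
      GT[[length(GT) + 1L]] <- g
    }
    if (!length(rows)) {
      vs <- variant_set(integer(), character(), character(),
                        GT = matrix(NA_integer_, 0, n_acc),
                        DP = matrix(NA_integer_, 0, n_acc),
                        samples = sprintf("acc%03d", seq_len(n_acc)))
      return(list(variants = vs, truth = data.frame()))
    }
    truth <- do.call(rbind, rows)
    ord <- order(truth$pos0)
    truth <- truth[ord, ]; GT <- GT[ord]
    gt <- do.call(rbind, GT)
    seq_v <- strsplit(genome$sequence, "")[[1]]
    ref <- alt <- character(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      if (truth$vclass[i] == "SNP") {
        ref[i] <- truth$ancestral[i]; alt[i] <- truth$derived[i]
      } else {
        ## 1-bp deletion: REF = base + deleted base, ALT = base
        ref[i] <- paste0(seq_v[truth$pos0[i] + 1L], seq_v[truth$pos0[i] + 2L])
        alt[i] <- seq_v[truth$pos0[i] + 1L]
      }
    }
    DP <- matrix(rpois(nrow(truth) * n_acc, config$coverage_mean),
                 nrow(truth), n_acc)
    AD_ALT <- ifelse(gt == 1L, DP, 0L)
    vs <- variant_set(truth$pos0, ref, alt, vclass = truth$vclass,
                      GT = gt, DP = DP, AD_ALT = AD_ALT,
                      samples = sprintf("acc%03d", seq_len(n_acc)))
    list(variants = vs, truth = truth)
  })
}

#' Simulate a diverged outgroup with true alignment blocks
#'
#' Mutates the reference (the ancestor of the simulated population) at the
#' configured divergence, inserts occasional short indels, and returns
#' gapped alignment blocks tiling the genome — the ground truth a local
#' aligner would ideally recover — for exercising outgroup polarization
#' including gap projection.
#'
#' @param genome `annotated_genome`.
#' @param config [sim_config()].
#' @param seed integer seed.
#' @param block_bp alignment block tiling size (default 2000).
#' @return list with `outgroup_sequence` and `blocks` (rows as produced by
#'   [alignment_block()]).
#' @export
simulate_outgroup <- function(genome, config = sim_config(), seed = 1L,
                              block_bp = 2000L) {
  local_seed(seed, {
    refv <- strsplit(genome$sequence, "")[[1]]
    L <- length(refv)
    r <- runif(L)
    ref_piece <- refv
    out_piece <- refv
    mut <- which(r < config$outgroup_divergence)
    for (i in mut) out_piece[i] <- sample(setdiff(c("A", "C", "G", "T"), refv[i]), 1)
    del <- which(r >= config$outgroup_divergence &
                 r < config$outgroup_divergence + config$outgroup_indel_rate / 2)
    out_piece[del] <- "-"
    ins <- which(r >= config$outgroup_divergence + config$outgroup_indel_rate / 2 &
                 r < config$outgroup_divergence + config$outgroup_indel_rate)
    for (i in ins) {
      n_ins <- sample(3, 1)
      ref_piece[i] <- paste0(strrep("-", n_ins), refv[i])
      out_piece[i] <- paste0(paste(sample(c("A", "C", "G", "T"), n_ins,
                                          replace = TRUE), collapse = ""), refv[i])
    }
    ref_aln <- strsplit(paste(ref_piece, collapse = ""), "")[[1]]
    out_aln <- strsplit(paste(out_piece, collapse = ""), "")[[1]]
    ## split the genome-wide alignment into blocks at reference coordinates
    ref_cum <- cumsum(ref_aln != "-")
    out_cum <- cumsum(out_aln != "-")
    starts <- seq(0L, L - 1L, by = block_bp)
    blocks <- do.call(rbind, lapply(starts, function(s) {
      e <- min(s + block_bp, L)
      cols <- which(ref_cum >= s + 1L & ref_cum <= e & !(ref_aln == "-" & ref_cum == s))
      alignment_block(
        ref_start = s,
        out_start = if (length(cols)) out_cum[cols[1]] - (out_aln[cols[1]] != "-") else 0L,
        ref_aln = paste(ref_aln[cols], collapse = ""),
        out_aln = paste(out_aln[cols], collapse = ""))
    }))
    list(outgroup_sequence = paste(out_aln[out_aln != "-"], collapse = ""),
         blocks = blocks)
  })
}
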