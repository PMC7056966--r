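## Variant filtering, polarization (outgroup projection and minor-allele
## frequency), mutation-spectrum and functional-density tables, and the
## MA-line unique-variant / heteroplasmy screens.

#' Filter variants on coverage depth
#'
#' Per-sample calls are masked (genotype set to missing) where the site depth
#' is below `min_depth` or outside `[low_mult, high_mult]` times the
#' genome-wide median coverage; sites left with no passing call are dropped.
#' These thresholds guard against variants driven by low-frequency homologous
#' sequences (nuclear insertions of mitochondrial DNA) or repeat mis-mapping.
#'
#' @param vs `variant_set`.
#' @param median_coverage genome-wide median coverage, a scalar or one value
#'   per sample.
#' @param min_depth site depth floor (default 50).
#' @param low_mult,high_mult retained depth range as multiples of the median
#'   (defaults 0.5 and 3).
#' @return filtered `variant_set` (a subset of the input sites).
#' @export
filter_variants <- function(vs, median_coverage, min_depth = 50,
                            low_mult = 0.5, high_mult = 3) {
  stopifnot(inherits(vs, "variant_set"), all(median_coverage > 0))
  if (vs$n_sites == 0L) return(vs)
  med <- rep_len(median_coverage, length(vs$samples))
  pass <- vs$DP >= min_depth &
    sweep(vs$DP, 2, low_mult * med, ">=") &
    sweep(vs$DP, 2, high_mult * med, "<=")
  pass[is.na(pass)] <- FALSE
  vs$GT[!pass] <- NA_integer_
  keep <- which(rowSums(!is.na(vs$GT) & vs$GT > 0L) > 0L)
  subset_variant_set(vs, keep)
}

## per-site allele counts over non-missing genotype calls
allele_counts <- function(vs, i) {
  gt <- vs$GT[i, ]
  gt <- gt[!is.na(gt)]
  alleles <- c(vs$ref[i], vs$alt1[i], vs$alt2[i])
  counts <- vapply(0:2, function(a) sum(gt == a), integer(1))
  names(counts) <- alleles
  counts[!is.na(alleles)]
}

#' Minor-allele frequency per site
#'
#' Computed over samples with non-missing calls: 1 minus the frequency of
#' the most common allele (so triallelic sites report the total minor
#' fraction).
#'
#' @param vs `variant_set`.
#' @return numeric vector, one value per site (NA where no calls).
#' @export
minor_allele_frequency <- function(vs) {
  vapply(seq_len(vs$n_sites), function(i) {
    counts <- allele_counts(vs, i)
    tot <- sum(counts)
    if (tot == 0L) return(NA_real_)
    1 - max(counts) / tot
  }, numeric(1))
}

## empty polarization frame
empty_polarization <- function() {
  data.frame(site = integer(), pos0 = integer(), ancestral = character(),
             derived = character(), method = character(), conflict = logical(),
             stringsAsFactors = FALSE)
}

#' Polarize variants by minor-allele frequency
#'
#' Assumes the derived allele is typically rare: at each SNP site the
#' highest-frequency allele is called ancestral and every other observed
#' allele is a derived change.  Exact 50/50 ties are left unpolarized.
#'
#' @param vs `variant_set` (SNP sites only are polarized; indels and MNVs are
#'   skipped).
#' @return data.frame with one row per (site, derived allele): `site`,
#'   `pos0`, `ancestral`, `derived`, `method` (`"maf"` or `"unpolarized"`),
#'   `conflict`.
#' @export
polarize_by_maf <- function(vs) {
  rows <- lapply(seq_len(vs$n_sites), function(i) {
    if (vs$vclass[i] != "SNP") return(NULL)
    counts <- allele_counts(vs, i)
    if (sum(counts) == 0L) stop("no non-missing calls at site ", i)
    observed <- counts[counts > 0L]
    if (length(observed) < 2L) return(NULL)   # invariant among callable samples
    top <- max(observed)
    majors <- names(observed)[observed == top]
    if (length(majors) > 1L)
      return(data.frame(site = i, pos0 = vs$pos0[i], ancestral = NA_character_,
                        derived = NA_character_, method = "unpolarized",
                        conflict = FALSE, stringsAsFactors = FALSE))
    anc <- majors
    derived <- setdiff(names(observed), anc)
    data.frame(site = i, pos0 = vs$pos0[i], ancestral = anc, derived = derived,
               method = "maf", conflict = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty_polarization()), rows))
  rownames(out) <- NULL
  out
}

#' Build an alignment block between reference and outgroup
#'
#' @param ref_start,out_start 0-based starts of the aligned region in the
#'   reference and outgroup genomes.
#' @param ref_aln,out_aln aligned sequences of equal length, gaps as `-`.
#' @param strand outgroup strand (`+` supported).
#' @return data.frame row describing the block, with percent identity
#'   computed over the alignment (gaps count as mismatches).
#' @export
alignment_block <- function(ref_start, out_start, ref_aln, out_aln, strand = "+") {
  stopifnot(nchar(ref_aln) == nchar(out_aln))
  a <- strsplit(toupper(ref_aln), "")[[1]]
  b <- strsplit(toupper(out_aln), "")[[1]]
  ident <- sum(a == b & a != "-") / length(a)
  data.frame(ref_start = ref_start, out_start = out_start,
             ref_aln = ref_aln, out_aln = out_aln, strand = strand,
             length = sum(a != "-"), identity = ident,
             stringsAsFactors = FALSE)
}

## project a 0-based reference position through a gapped alignment block;
## returns the outgroup base, or NA if the position is not in the block or
## falls opposite a gap.
project_outgroup_base <- function(block, pos0) {
  a <- strsplit(toupper(block$ref_aln), "")[[1]]
  b <- strsplit(toupper(block$out_aln), "")[[1]]
  ref_pos <- block$ref_start + cumsum(a != "-") - 1L
  idx <- which(a != "-" & ref_pos == pos0)
  if (!length(idx)) return(NA_character_)
  base <- b[idx[1]]
  if (base == "-") NA_character_ else base
}

#' Polarize variants by outgroup projection
#'
#' Projects each SNP position through gapped reference/outgroup alignment
#' blocks (minimum 400 bp and 90% identity enforced); when the outgroup base
#' equals one observed allele, that allele is ancestral.  Positions covered
#' by no qualifying block, falling in an alignment gap, or where the outgroup
#' base matches no observed allele are left unpolarized.  Overlapping blocks
#' giving conflicting outgroup bases also yield unpolarized, flagged calls.
#'
#' @param vs `variant_set`.
#' @param blocks data.frame of [alignment_block()] rows.
#' @param min_length,min_identity block qualification thresholds (defaults
#'   400 bp and 0.90).
#' @return polarization data.frame as in [polarize_by_maf()], `method` one of
#'   `"outgroup"`/`"unpolarized"`.
#' @export
polarize_by_outgroup <- function(vs, blocks, min_length = 400, min_identity = 0.90) {
  blocks <- blocks[blocks$length >= min_length & blocks$identity >= min_identity, ,
                   drop = FALSE]
  rows <- lapply(seq_len(vs$n_sites), function(i) {
    if (vs$vclass[i] != "SNP") return(NULL)
    unpol <- function(conflict = FALSE)
      data.frame(site = i, pos0 = vs$pos0[i], ancestral = NA_character_,
                 derived = NA_character_, method = "unpolarized",
                 conflict = conflict, stringsAsFactors = FALSE)
    bases <- character(0)
    for (j in seq_len(nrow(blocks))) {
      b <- project_outgroup_base(blocks[j, ], vs$pos0[i])
      if (!is.na(b)) bases <- c(bases, b)
    }
    bases <- unique(bases)
    if (length(bases) == 0L) return(unpol())
    if (length(bases) > 1L) return(unpol(conflict = TRUE))
    counts <- allele_counts(vs, i)
    observed <- names(counts)[counts > 0L]
    if (length(observed) < 2L) return(NULL)
    if (!bases %in% observed) return(unpol())
    derived <- setdiff(observed, bases)
    data.frame(site = i, pos0 = vs$pos0[i], ancestral = bases, derived = derived,
               method = "outgroup", conflict = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty_polarization()), rows))
  rownames(out) <- NULL
  out
}

#' Agreement between two polarization methods
#'
#' @param pol_a,pol_b polarization data.frames for the same variant set.
#' @return list with `agreement` (fraction of doubly-polarized sites where
#'   both methods name the same derived allele set), `n_compared`.
#' @export
polarization_agreement <- function(pol_a, pol_b) {
  key <- function(p) {
    p <- p[p$method != "unpolarized", , drop = FALSE]
    tapply(p$derived, p$site, function(d) paste(sort(d), collapse = ","))
  }
  a <- key(pol_a); b <- key(pol_b)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) {
    warning("no sites polarized by both methods")
    return(list(agreement = NA_real_, n_compared = 0L))
  }
  list(agreement = mean(a[shared] == b[shared]), n_compared = length(shared))
}

BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

#' Directional mutation spectrum from polarized SNPs
#'
#' @param polarized polarization data.frame (rows with `method ==
#'   "unpolarized"` are ignored).
#' @return list with `directional` (4x4 ancestral x derived count matrix),
#'   `pair_classes` (six strand-symmetric substitution classes),
#'   `transitions`, `transversions`, `ts_tv_ratio`, `at_gaining`,
#'   `at_losing`, `at_neutral`, `at_bias_ratio` (gaining/losing; NA with all
#'   ratios when a denominator is zero).
#' @export
mutation_spectrum <- function(polarized) {
  p <- polarized[polarized$method != "unpolarized", , drop = FALSE]
  p <- p[p$ancestral %in% BASES & p$derived %in% BASES, , drop = FALSE]
  directional <- matrix(0L, 4, 4, dimnames = list(ancestral = BASES, derived = BASES))
  for (i in seq_len(nrow(p)))
    directional[p$ancestral[i], p$derived[i]] <-
      directional[p$ancestral[i], p$derived[i]] + 1L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pair_of <- function(b) switch(b, A = "A:T", T = "T:A", G = "G:C", C = "C:G")
  pair_class <- function(anc, der) {
    ## canonicalise to the strand where the ancestral base is G or A, so
    ## e.g. T->A and A->T both read A:T->T:A
    if (anc %in% c("C", "T")) { anc <- comp[[anc]]; der <- comp[[der]] }
    sprintf("%s->%s", if (anc == "G") "G:C" else "A:T", pair_of(der))
  }
  classes <- c("G:C->A:T", "G:C->T:A", "G:C->C:G", "A:T->G:C", "A:T->C:G", "A:T->T:A")
  pair_counts <- setNames(integer(6), classes)
  ts <- tv <- gain <- lose <- neutral <- 0L
  if (nrow(p)) for (i in seq_len(nrow(p))) {
    anc <- p$ancestral[i]; der <- p$derived[i]
    cl <- pair_class(anc, der)
    pair_counts[cl] <- pair_counts[cl] + 1L
    if ((anc %in% PURINES) == (der %in% PURINES)) ts <- ts + 1L else tv <- tv + 1L
    anc_at <- anc %in% c("A", "T"); der_at <- der %in% c("A", "T")
    if (!anc_at && der_at) gain <- gain + 1L
    else if (anc_at && !der_at) lose <- lose + 1L
    else neutral <- neutral + 1L
  }
  list(directional = directional, pair_classes = pair_counts,
       transitions = ts, transversions = tv,
       ts_tv_ratio = if (tv > 0) ts / tv else NA_real_,
       at_gaining = gain, at_losing = lose, at_neutral = neutral,
       at_bias_ratio = if (lose > 0) gain / lose else NA_real_,
       n = nrow(p))
}

#' Per-functional-class variant density table
#'
#' Tabulates SNP and indel counts, per-site densities and mean minor-allele
#' frequencies per functional class, splitting CDS SNPs into synonymous and
#' nonsynonymous against the fractional site totals.  Multi-allelic SNP sites
#' contribute one count per observed alternate allele (so the SNP total can
#' exceed the site total).  Also reports the fold difference in SNP density
#' between genes (CDS + rRNA + tRNA) and intergenic regions, and the
#' chi-square contrast of synonymous versus intergenic density.
#'
#' @param vs filtered `variant_set`.
#' @param partition [partition_positions()] result covering the genome.
#' @param genome `annotated_genome` (needed to translate CDS variants).
#' @return list with `table` (data.frame, one row per class plus
#'   Total), `genic_intergenic_fold`, `syn_vs_intergenic_chisq`.
#' @export
density_by_class <- function(vs, partition, genome) {
  classes <- c("Protein Coding", "Nonsynonymous", "Synonymous", "rRNA", "tRNA",
               "Pseudogene", "Intron", "Intergenic")
  sites <- c(`Protein Coding` = unname(partition$totals["CDS"]),
             Nonsynonymous = partition$nonsyn_sites,
             Synonymous = partition$syn_sites,
             rRNA = unname(partition$totals["rRNA"]),
             tRNA = unname(partition$totals["tRNA"]),
             Pseudogene = unname(partition$totals["pseudogene"]),
             Intron = unname(partition$totals["intron"]),
             Intergenic = unname(partition$totals["intergenic"]))
  snp <- indel <- setNames(numeric(length(classes)), classes)
  maf_snp <- maf_indel <- setNames(vector("list", length(classes)), classes)
  maf_all <- minor_allele_frequency(vs)
  for (i in seq_len(vs$n_sites)) {
    pos <- vs$pos0[i]
    if (pos < 0 || pos >= partition$genome_length)
      stop("variant position ", pos, " not covered by the partition")
    cls <- as.character(partition$class[pos + 1L])
    if (vs$vclass[i] == "SNP") {
      alts <- c(vs$alt1[i], vs$alt2[i])
      counts <- allele_counts(vs, i)
      for (alt in alts[!is.na(alts)]) {
        if (!alt %in% names(counts) || counts[alt] == 0L) next
        row <- if (cls == "CDS") {
          eff <- classify_variant_effect(genome, pos, vs$ref[i], alt, partition)
          if (eff == "synonymous") "Synonymous" else "Nonsynonymous"
        } else switch(cls, rRNA = "rRNA", tRNA = "tRNA",
                      pseudogene = "Pseudogene", intron = "Intron", "Intergenic")
        snp[row] <- snp[row] + 1
        maf_snp[[row]] <- c(maf_snp[[row]], maf_all[i])
      }
    } else if (vs$vclass[i] == "indel") {
      row <- switch(cls, CDS = "Protein Coding", rRNA = "rRNA", tRNA = "tRNA",
                    pseudogene = "Pseudogene", intron = "Intron", "Intergenic")
      indel[row] <- indel[row] + 1
      maf_indel[[row]] <- c(maf_indel[[row]], maf_all[i])
    }
    ## MNVs carry a positional class but are excluded from SNP counts
  }
  snp["Protein Coding"] <- snp["Nonsynonymous"] + snp["Synonymous"]
  maf_snp["Protein Coding"] <- list(c(maf_snp[["Nonsynonymous"]],
                                      maf_snp[["Synonymous"]]))
  mean_or_na <- function(x) if (length(x)) mean(x, na.rm = TRUE) else NA_real_
  tab <- data.frame(
    class = classes, sites = unname(sites[classes]), snps = unname(snp),
    snps_per_site = unname(ifelse(sites[classes] > 0, snp / sites[classes], NA)),
    snp_maf = vapply(maf_snp, mean_or_na, numeric(1)),
    indels = unname(indel),
    indels_per_site = unname(ifelse(sites[classes] > 0, indel / sites[classes], NA)),
    indel_maf = vapply(maf_indel, mean_or_na, numeric(1)),
    stringsAsFactors = FALSE)
  sub <- tab$class != "Protein Coding"   # avoid double-counting syn/nonsyn split
  total <- data.frame(class = "Total",
                      sites = partition$genome_length,
                      snps = sum(tab$snps[sub]),
                      snps_per_site = sum(tab$snps[sub]) / partition$genome_length,
                      snp_maf = mean_or_na(unlist(maf_snp[classes[sub]])),
                      indels = sum(tab$indels[sub]),
                      indels_per_site = sum(tab$indels[sub]) / partition$genome_length,
                      indel_maf = mean_or_na(unlist(maf_indel[classes[sub]])))
  tab <- rbind(tab, total)
  list(table = tab,
       genic_intergenic_fold = genic_intergenic_fold(tab),
       syn_vs_intergenic_chisq = syn_vs_intergenic_chisq(tab))
}

#' Genic vs intergenic SNP density fold difference
#'
#' Ratio of intergenic SNP density to the pooled density of protein-coding,
#' rRNA and tRNA sequence.
#'
#' @param density_table the `table` element of [density_by_class()] (or any
#'   data.frame with `class`, `sites`, `snps`).
#' @return fold ratio (intergenic / genic density).
#' @export
genic_intergenic_fold <- function(density_table) {
  t <- density_table
  genic <- t$class %in% c("Protein Coding", "rRNA", "tRNA")
  genic_d <- sum(t$snps[genic]) / sum(t$sites[genic])
  inter_d <- t$snps[t$class == "Intergenic"] / t$sites[t$class == "Intergenic"]
  unname(inter_d / genic_d)
}

#' Chi-square contrast of synonymous vs intergenic SNP density
#'
#' 2x2 homogeneity test of variant vs invariant site counts between
#' synonymous positions and intergenic regions (delegates to
#' [chi_square_2x2()], no continuity correction).
#'
#' @inheritParams genic_intergenic_fold
#' @return list with `statistic`, `dof`, `p`.
#' @export
syn_vs_intergenic_chisq <- function(density_table) {
  t <- density_table
  syn <- t[t$class == "Synonymous", ]
  int <- t[t$class == "Intergenic", ]
  m <- matrix(c(syn$snps, syn$sites - syn$snps,
                int$snps, int$sites - int$snps), nrow = 2, byrow = TRUE)
  tryCatch(chi_square_2x2(round(m)),
           error = function(e) {
             warning("chi-square contrast untestable: ", conditionMessage(e))
             list(statistic = NA_real_, dof = NA_integer_, p = NA_real_)
           })
}

#' Variants unique to a single line
#'
#' The de novo screen of a mutation-accumulation design: a variant whose
#' carriers all belong to exactly one line is a candidate de novo mutation
#' (variants shared across lines are ancestral heteroplasmies or artifacts).
#'
#' @param vs `variant_set`.
#' @param sample_line named character vector mapping sample name to line.
#' @return data.frame with `site`, `pos0`, `line`, `carriers`
#'   (comma-separated sample names), `max_fraction` (largest alt-allele read
#'   fraction among carriers, NA without depth data).
#' @export
unique_line_variants <- function(vs, sample_line) {
  if (!all(vs$samples %in% names(sample_line)))
    stop("unmapped sample(s): ",
         paste(setdiff(vs$samples, names(sample_line)), collapse = ", "))
  lines <- sample_line[vs$samples]
  if (length(unique(lines)) < 2L) stop("need >= 2 lines")
  rows <- lapply(seq_len(vs$n_sites), function(i) {
    carriers <- which(!is.na(vs$GT[i, ]) & vs$GT[i, ] > 0L)
    if (!length(carriers)) return(NULL)
    carrier_lines <- unique(lines[carriers])
    if (length(carrier_lines) != 1L) return(NULL)
    fr <- vs$AD_ALT[i, carriers] / vs$DP[i, carriers]
    data.frame(site = i, pos0 = vs$pos0[i], vclass = vs$vclass[i],
               line = carrier_lines,
               carriers = paste(vs$samples[carriers], collapse = ","),
               max_fraction = if (all(is.na(fr))) NA_real_ else max(fr, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site = integer(), pos0 = integer(), vclass = character(),
                      line = character(), carriers = character(),
                      max_fraction = numeric())
  rownames(out) <- NULL
  out
}

#' Flag heteroplasmic candidate variants
#'
#' A sample is flagged heteroplasmic at a site when its alternate-allele read
#' fraction is at least `min_fraction` but below 1 (fixed differences are not
#' heteroplasmies).
#'
#' @param vs `variant_set` with allele depths.
#' @param min_fraction detection floor (default 0.10).
#' @return data.frame with `site`, `pos0`, `sample`, `fraction`.
#' @export
heteroplasmic_candidates <- function(vs, min_fraction = 0.10) {
  rows <- lapply(seq_len(vs$n_sites), function(i) {
    dp <- vs$DP[i, ]; ad <- vs$AD_ALT[i, ]
    usable <- !is.na(dp) & !is.na(ad)
    if (any(usable & dp == 0)) {
      warning("zero total depth at site ", i, "; sample(s) skipped")
      usable <- usable & dp > 0
    }
    fr <- ad[usable] / dp[usable]
    hits <- which(fr >= min_fraction & fr < 1)
    if (!length(hits)) return(NULL)
    data.frame(site = i, pos0 = vs$pos0[i],
               sample = vs$samples[usable][hits], fraction = fr[hits],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site = integer(), pos0 = integer(), sample = character(),
                      fraction = numeric())
  rownames(out) <- NULL
  out
}
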