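## Functional partitioning of the circular mitogenome and codon-level site
## accounting.  Internal coordinates are 0-based half-open throughout; GFF3
## (1-based closed) and VCF (1-based) are converted at the I/O boundary.

FEATURE_KINDS <- c("CDS", "rRNA", "tRNA", "intron", "pseudogene")
POSITION_CLASSES <- c(FEATURE_KINDS, "intergenic")

#' Construct an annotated circular mitogenome
#'
#' @param sequence genome sequence: a single character string or `DNAString`
#'   (A/C/G/T/N).
#' @param features data.frame with columns `kind` (one of CDS, rRNA, tRNA,
#'   intron, pseudogene), `start`, `end` (0-based half-open), `strand`
#'   (`+`/`-`), `gene` (parent gene id) and optional `phase` for CDS parts.
#' @param mtpt data.frame of plastid-derived insertion intervals (`start`,
#'   `end`, 0-based half-open), excluded from coverage windows.
#' @param repeats data.frame of repeat pairs (see [find_repeat_pairs()]),
#'   or NULL.
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(sequence, features = NULL, mtpt = NULL, repeats = NULL) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L, nchar(sequence) > 0L)
  if (grepl("[^ACGTN]", sequence)) stop("sequence may contain only A/C/G/T/N")
  L <- nchar(sequence)
  if (is.null(features))
    features <- data.frame(kind = character(), start = integer(), end = integer(),
                           strand = character(), gene = character(),
                           phase = integer())
  features <- as.data.frame(features)
  if (!"phase" %in% names(features)) features$phase <- 0L
  if (nrow(features)) {
    stopifnot(all(features$kind %in% FEATURE_KINDS),
              all(features$strand %in% c("+", "-")),
              all(features$start < features$end))
    if (any(features$start < 0 | features$end > L))
      stop("feature outside genome bounds [0, ", L, ")")
    cds_len <- tapply(features$end - features$start,
                      ifelse(features$kind == "CDS", features$gene, NA), sum)
    bad <- names(cds_len)[!is.na(names(cds_len)) & cds_len %% 3 != 0]
    if (length(bad))
      stop("CDS length not divisible by 3 for gene(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(mtpt)) mtpt <- data.frame(start = integer(), end = integer())
  structure(list(sequence = sequence, length = L, features = features,
                 mtpt = mtpt, repeats = repeats, circular = TRUE),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome: %d bp circular, %d features, %d mtpt intervals\n",
              x$length, nrow(x$features), nrow(x$mtpt)))
  if (nrow(x$features)) print(table(x$features$kind))
  invisible(x)
}

#' Partition every genome position into a functional class
#'
#' Each position receives exactly one class.  Overlaps are resolved by the
#' precedence CDS > tRNA > rRNA > intron > pseudogene (most constrained class
#' wins); unannotated positions are intergenic.  For CDS, fractional
#' synonymous and nonsynonymous site totals are accumulated per codon.
#'
#' @param genome `annotated_genome`.
#' @param precedence character vector ordering the five feature kinds from
#'   highest to lowest priority.
#' @return object of class `partition_map`: `class` (factor, one entry per
#'   position), `totals` (named per-class site counts summing to the genome
#'   length), `syn_sites`, `nonsyn_sites`.
#' @export
partition_positions <- function(genome, precedence = FEATURE_KINDS) {
  stopifnot(inherits(genome, "annotated_genome"),
            setequal(precedence, FEATURE_KINDS))
  L <- genome$length
  cls <- rep("intergenic", L)
  feats <- genome$features
  ## paint lowest priority first so higher priority overwrites
  for (kind in rev(precedence)) {
    rows <- feats[feats$kind == kind, , drop = FALSE]
    for (i in seq_len(nrow(rows)))
      cls[(rows$start[i] + 1L):rows$end[i]] <- kind
  }
  totals <- setNames(integer(length(POSITION_CLASSES)), POSITION_CLASSES)
  tab <- table(cls)
  totals[names(tab)] <- as.integer(tab)
  syn <- nonsyn <- 0
  for (gene in unique(feats$gene[feats$kind == "CDS"])) {
    cds <- coding_sequence(genome, gene)
    counts <- count_syn_nonsyn_sites(cds)
    syn <- syn + counts[["syn_sites"]]
    nonsyn <- nonsyn + counts[["nonsyn_sites"]]
  }
  structure(list(class = factor(cls, levels = POSITION_CLASSES),
                 totals = totals, syn_sites = syn, nonsyn_sites = nonsyn,
                 genome_length = L),
            class = "partition_map")
}

#' @export
print.partition_map <- function(x, ...) {
  cat(sprintf("partition_map over %d bp\n", x$genome_length))
  print(x$totals)
  cat(sprintf("CDS sites: %.2f synonymous + %.2f nonsynonymous\n",
              x$syn_sites, x$nonsyn_sites))
  invisible(x)
}

## Assemble the in-frame coding sequence of a gene from its CDS parts,
## concatenated in annotation order on the coding strand (handles trans-
## spliced and multi-exon genes).  Returns the coding-strand nucleotides.
coding_sequence <- function(genome, gene) {
  parts <- genome$features[genome$features$kind == "CDS" &
                           genome$features$gene == gene, , drop = FALSE]
  if (!nrow(parts)) stop("no CDS parts for gene ", gene)
  pieces <- vapply(seq_len(nrow(parts)), function(i) {
    s <- substr(genome$sequence, parts$start[i] + 1L, parts$end[i])
    if (parts$strand[i] == "-") revcomp(s) else s
  }, character(1))
  paste0(pieces, collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

translate_codon <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[codon]
  if (is.na(aa)) stop("cannot translate codon ", codon)
  unname(aa)
}

#' Fractional synonymous and nonsynonymous site counts for a coding sequence
#'
#' For every codon, each of the three positions contributes
#' `(synonymous single-base changes at that position) / 3` synonymous sites
#' and the complement nonsynonymous sites, in the Nei–Gojobori style that
#' accounts for the partial degeneracy of two- and three-member codon
#' families.  Changes creating a stop codon count as nonsynonymous.  A
#' trailing stop codon, if present, is removed before counting.
#'
#' @param cds_sequence in-frame coding nucleotides (length divisible by 3).
#' @return named numeric vector `c(syn_sites=, nonsyn_sites=)`; the two sum
#'   to 3 x (number of counted codons).
#' @examples
#' count_syn_nonsyn_sites("ATGGCTTGG")  # Met-Ala-Trp: 1 synonymous site
#' @export
count_syn_nonsyn_sites <- function(cds_sequence) {
  cds_sequence <- toupper(as.character(cds_sequence))
  n <- nchar(cds_sequence)
  if (n %% 3 != 0) stop("coding sequence length not divisible by 3")
  if (grepl("[^ACGT]", cds_sequence)) stop("coding sequence must be A/C/G/T only")
  codons <- substring(cds_sequence, seq(1, n, 3), seq(3, n, 3))
  aas <- Biostrings::GENETIC_CODE[codons]
  if (length(codons) && aas[length(codons)] == "*") {
    codons <- codons[-length(codons)]
    aas <- aas[-length(aas)]
  }
  if (any(aas == "*"))
    stop("internal stop codon at codon index ", which(aas == "*")[1])
  tab <- syn_site_table()
  syn <- sum(tab[codons])
  c(syn_sites = syn, nonsyn_sites = 3 * length(codons) - syn)
}

## Per-codon fractional synonymous sites, cached: for each codon, over the 9
## single-base alternatives, the fraction preserving the amino acid, times 3.
syn_site_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    out <- vapply(names(code), function(codon) {
      aa <- code[[codon]]
      s <- 0
      for (p in 1:3) {
        orig <- substr(codon, p, p)
        for (b in setdiff(bases, orig)) {
          mut <- codon
          substr(mut, p, p) <- b
          if (code[[mut]] == aa) s <- s + 1 / 3
        }
      }
      s
    }, numeric(1))
    cache <<- out
    out
  }
})

#' Classify the functional effect of a single-nucleotide variant
#'
#' Positions inside a CDS are classified by translating the reference and
#' alternate codons on the coding strand (reverse-complementing for minus
#' strand genes, with spliced codon assembly across introns); other positions
#' return their partition class.
#'
#' @param genome `annotated_genome`.
#' @param position 0-based genome position.
#' @param ref_allele,alt_allele single uppercase bases; `ref_allele` must
#'   match the genome.
#' @param partition optional precomputed [partition_positions()] result.
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"rRNA"`, `"tRNA"`,
#'   `"intron"`, `"pseudogene"`, `"intergenic"`.
#' @export
classify_variant_effect <- function(genome, position, ref_allele, alt_allele,
                                    partition = NULL) {
  stopifnot(inherits(genome, "annotated_genome"),
            position >= 0, position < genome$length,
            nchar(ref_allele) == 1L, nchar(alt_allele) == 1L)
  genome_base <- substr(genome$sequence, position + 1L, position + 1L)
  if (genome_base != ref_allele)
    stop(sprintf("ref allele mismatch at %d: genome has %s, variant says %s",
                 position, genome_base, ref_allele))
  if (is.null(partition)) partition <- partition_positions(genome)
  cls <- as.character(partition$class[position + 1L])
  if (cls != "CDS") return(cls)

  ## locate the CDS part (precedence already put this position in a CDS)
  feats <- genome$features
  hit <- which(feats$kind == "CDS" & feats$start <= position & position < feats$end)
  part <- hit[1]
  gene <- feats$gene[part]
  parts <- which(feats$kind == "CDS" & feats$gene == gene)
  ## coding-strand index of this position within the assembled CDS
  idx <- 0L
  for (j in parts) {
    if (j == part) {
      within <- if (feats$strand[j] == "+") position - feats$start[j]
                else feats$end[j] - 1L - position
      idx <- idx + within
      break
    }
    idx <- idx + feats$end[j] - feats$start[j]
  }
  cds <- coding_sequence(genome, gene)
  strand <- feats$strand[part]
  ref_c <- if (strand == "+") ref_allele else revcomp(ref_allele)
  alt_c <- if (strand == "+") alt_allele else revcomp(alt_allele)
  if (substr(cds, idx + 1L, idx + 1L) != ref_c)
    stop("internal error: coding sequence disagrees with reference allele")
  codon_i <- idx %/% 3L
  codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  mut <- codon
  substr(mut, idx %% 3L + 1L, idx %% 3L + 1L) <- alt_c
  if (translate_codon(codon) == translate_codon(mut)) "synonymous" else "nonsynonymous"
}

#' GC fraction of a sequence window
#'
#' @param window_sequence character string; N bases are ignored in both
#'   numerator and denominator.
#' @return (G+C)/(A+C+G+T), or NA with a warning for an all-N window.
#' @export
gc_content <- function(window_sequence) {
  window_sequence <- toupper(as.character(window_sequence))
  stopifnot(nchar(window_sequence) > 0L)
  counts <- table(strsplit(window_sequence, "")[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0) {
    warning("all-N window: GC content undefined")
    return(NA_real_)
  }
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  gc / acgt
}

#' Enumerate long homopolymer runs in a genome sequence
#'
#' @param sequence character string.
#' @param min_run runs strictly longer than this count (default 7, i.e. 8+ bp).
#' @return data.frame with `start` (0-based), `length`, `base`.
#' @export
homopolymer_runs <- function(sequence, min_run = 7L) {
  sequence <- toupper(as.character(sequence))
  r <- rle(strsplit(sequence, "")[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths > min_run & r$values %in% c("A", "C", "G", "T")
  data.frame(start = (ends - r$lengths)[keep], length = r$lengths[keep],
             base = r$values[keep], stringsAsFactors = FALSE)
}

#' Count long homopolymer runs starting within a window
#'
#' Runs spanning a window boundary are counted once, in the window containing
#' the run's first base.
#'
#' @param runs output of [homopolymer_runs()] for the whole sequence (or a
#'   sequence string, in which case runs are computed with `min_run`).
#' @param start,end 0-based half-open window.
#' @param min_run threshold used when `runs` is a sequence string.
#' @return integer count.
#' @export
homopolymer_count <- function(runs, start, end, min_run = 7L) {
  if (is.character(runs)) runs <- homopolymer_runs(runs, min_run)
  sum(runs$start >= start & runs$start < end)
}
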