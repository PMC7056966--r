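## Genome-side I/O: FASTA, GFF3, BED.  Internal coordinates are 0-based
## half-open; GFF3 (1-based closed) and BED (0-based half-open) are converted
## here and nowhere else.

#' Write a genome sequence to FASTA
#' @param genome `annotated_genome` (or character sequence).
#' @param path output path.
#' @param name sequence name used in the header.
#' @export
write_genome_fasta <- function(genome, path, name = "mito") {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence else as.character(genome)
  x <- Biostrings::DNAStringSet(setNames(seq, name))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a single-sequence FASTA
#' @param path FASTA path.
#' @return character string (the first sequence).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as.character(x[[1]])
}

#' Write genome features to GFF3
#' @param genome `annotated_genome`.
#' @param path output path.
#' @param seqname sequence name.
#' @export
write_features_gff3 <- function(genome, path, seqname = "mito") {
  feats <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand)
  S4Vectors::mcols(gr)$type <- feats$kind
  S4Vectors::mcols(gr)$ID <- sprintf("%s.%d", feats$gene, seq_len(nrow(feats)))
  S4Vectors::mcols(gr)$gene <- feats$gene
  S4Vectors::mcols(gr)$phase <- ifelse(feats$kind == "CDS", feats$phase, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read features from GFF3
#'
#' Only the five recognised types (CDS, rRNA, tRNA, intron, pseudogene) are
#' kept; coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 path.
#' @return feature data.frame as used by [annotated_genome()].
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% FEATURE_KINDS]
  md <- S4Vectors::mcols(gr)
  gene <- if ("gene" %in% names(md)) as.character(md$gene) else as.character(md$ID)
  phase <- if ("phase" %in% names(md)) suppressWarnings(as.integer(md$phase)) else 0L
  phase[is.na(phase)] <- 0L
  df <- data.frame(kind = as.character(md$type),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   gene = gene, phase = phase,
                   stringsAsFactors = FALSE)
  ## GFF rows come back in file order; keep that order (CDS parts are
  ## concatenated in annotation order when assembling coding sequence)
  df
}

#' Write intervals to BED
#' @param intervals data.frame with `start`, `end` (0-based half-open).
#' @param path output path.
#' @param seqname sequence name.
#' @export
write_bed <- function(intervals, path, seqname = "mito") {
  df <- data.frame(chrom = seqname, start = intervals$start, end = intervals$end)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read intervals from BED
#' @param path BED path.
#' @return data.frame with `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr))
}

#' Write repeat pairs to TSV
#' @param pairs repeat-pair data.frame (see [find_repeat_pairs()]).
#' @param path output path.
#' @export
write_repeat_pairs_tsv <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read repeat pairs from TSV
#' @param path TSV path written by [write_repeat_pairs_tsv()].
#' @return repeat-pair data.frame.
#' @export
read_repeat_pairs_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
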