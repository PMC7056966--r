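## Alignment I/O.  Internally alignments are a plain data.frame with 0-based
## positions; SAM (1-based) is converted at this boundary.  Plain-text SAM is
## always supported so no binary tooling is needed; BAM is read through the
## same interface.

## columns of the internal alignment frame
ALN_COLS <- c("qname", "flag", "pos", "mapq", "cigar", "mpos", "tlen", "seq")

## reference-space width of a CIGAR string (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write alignments to SAM
#'
#' @param alignments alignment data.frame (`qname`, `flag`, `pos` 0-based,
#'   `mapq`, `cigar`, `mpos` 0-based mate position, `tlen`, optional `seq`).
#' @param path output path (`.sam`).
#' @param genome_length reference length for the `@SQ` header.
#' @param seqname reference name.
#' @export
write_sam <- function(alignments, path, genome_length, seqname = "mito") {
  a <- alignments
  if (!"seq" %in% names(a)) a$seq <- "*"
  a$seq[is.na(a$seq)] <- "*"
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", seqname, as.integer(genome_length)))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                   a$qname, a$flag, seqname, a$pos + 1L, a$mapq, a$cigar,
                   "=", a$mpos + 1L, a$tlen, a$seq)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' @param path `.sam` or `.bam` path.
#' @return alignment data.frame with 0-based `pos`/`mpos`.
#' @export
read_alignments <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    suppressMessages(Rsamtools::asBam(path, destination = dest,
                                      overwrite = TRUE, indexDestination = FALSE))
  } else path
  what <- c("qname", "flag", "pos", "mapq", "cigar", "mpos", "isize", "seq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  data.frame(qname = res$qname, flag = res$flag, pos = res$pos - 1L,
             mapq = res$mapq, cigar = res$cigar, mpos = res$mpos - 1L,
             tlen = res$isize, seq = as.character(res$seq),
             stringsAsFactors = FALSE)
}

## flag helpers
flag_has <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L
FLAG_PAIRED <- 1L; FLAG_UNMAPPED <- 4L; FLAG_MREVERSE <- 32L
FLAG_REVERSE <- 16L; FLAG_READ1 <- 64L; FLAG_READ2 <- 128L; FLAG_DUP <- 1024L
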