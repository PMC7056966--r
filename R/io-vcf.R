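## Variant container and VCF I/O.  A variant_set stores one row per site
## (up to two alternate alleles, matching callers that report triallelic
## sites) plus per-sample genotype, site depth and alt-allele depth matrices.
## VCF is 1-based; internal positions are 0-based.

#' Construct a multi-sample variant set
#'
#' @param pos0 integer vector of 0-based site positions.
#' @param ref,alt1 reference / first alternate allele strings.
#' @param alt2 optional second alternate allele (NA where biallelic).
#' @param vclass variant class per site: `"SNP"`, `"indel"` or `"MNV"`.
#' @param GT genotype matrix (sites x samples; allele index 0/1/2, NA = no
#'   call).
#' @param DP site depth matrix (sites x samples).
#' @param AD_ALT first-alternate allele depth matrix (sites x samples).
#' @param samples sample names.
#' @return object of class `variant_set`.
#' @export
variant_set <- function(pos0, ref, alt1, alt2 = NULL, vclass = NULL,
                        GT, DP, AD_ALT = NULL, samples = colnames(GT)) {
  n <- length(pos0)
  GT <- as.matrix(GT); DP <- as.matrix(DP)
  if (is.null(alt2)) alt2 <- rep(NA_character_, n)
  if (is.null(vclass))
    vclass <- ifelse(nchar(ref) == 1L & nchar(alt1) == 1L, "SNP", "indel")
  if (is.null(AD_ALT)) AD_ALT <- matrix(NA_integer_, n, ncol(GT))
  AD_ALT <- as.matrix(AD_ALT)
  stopifnot(length(ref) == n, length(alt1) == n, length(alt2) == n,
            nrow(GT) == n, nrow(DP) == n, nrow(AD_ALT) == n,
            ncol(GT) == ncol(DP), ncol(DP) == ncol(AD_ALT))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(GT)))
  colnames(GT) <- colnames(DP) <- colnames(AD_ALT) <- samples
  structure(list(pos0 = as.integer(pos0), ref = toupper(ref),
                 alt1 = toupper(alt1), alt2 = toupper(alt2),
                 vclass = vclass, GT = GT, DP = DP, AD_ALT = AD_ALT,
                 samples = samples, n_sites = n),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples (%s)\n", x$n_sites,
              length(x$samples),
              paste(sprintf("%s %d", names(table(x$vclass)), table(x$vclass)),
                    collapse = ", ")))
  invisible(x)
}

## subset a variant_set by site index
subset_variant_set <- function(vs, idx) {
  variant_set(vs$pos0[idx], vs$ref[idx], vs$alt1[idx], vs$alt2[idx],
              vs$vclass[idx], vs$GT[idx, , drop = FALSE],
              vs$DP[idx, , drop = FALSE], vs$AD_ALT[idx, , drop = FALSE],
              samples = vs$samples)
}

#' Write a variant set to VCF 4.2
#'
#' Genotypes are written haploid (mitochondrial convention) with DP and AD
#' (reference plus each alternate) per sample.
#'
#' @param vs `variant_set`.
#' @param path output path.
#' @param seqname reference sequence name.
#' @export
write_vcf <- function(vs, path, seqname = "mito") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", seqname),
    "##INFO=<ID=VC,Number=1,Type=String,Description=\"Variant class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t"))
  rows <- vapply(seq_len(vs$n_sites), function(i) {
    alt <- if (is.na(vs$alt2[i])) vs$alt1[i] else paste(vs$alt1[i], vs$alt2[i], sep = ",")
    cells <- vapply(seq_along(vs$samples), function(s) {
      gt <- vs$GT[i, s]
      dp <- vs$DP[i, s]
      ad_alt <- vs$AD_ALT[i, s]
      if (is.na(gt) && is.na(dp)) return("./.:.:.")
      gt_s <- if (is.na(gt)) "." else as.character(gt)
      dp_s <- if (is.na(dp)) "." else as.character(dp)
      ad_s <- if (is.na(dp) || is.na(ad_alt)) "." else {
        ref_d <- max(0L, dp - ad_alt)
        if (is.na(vs$alt2[i])) paste(ref_d, ad_alt, sep = ",")
        else paste(ref_d, ad_alt, 0L, sep = ",")
      }
      paste(gt_s, dp_s, ad_s, sep = ":")
    }, character(1))
    paste(c(seqname, vs$pos0[i] + 1L, ".", vs$ref[i], alt, ".", ".",
            sprintf("VC=%s", vs$vclass[i]), "GT:DP:AD", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a multi-sample VCF into a variant_set
#'
#' Uses VariantAnnotation; keeps up to two alternate alleles per site.
#'
#' @param path VCF path.
#' @return `variant_set`.
#' @export
read_vcf <- function(path) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  samples <- colnames(vcf)
  if (n == 0L)
    return(variant_set(integer(), character(), character(),
                       GT = matrix(NA_integer_, 0, length(samples)),
                       DP = matrix(NA_integer_, 0, length(samples)),
                       samples = samples))
  ref <- as.character(rr$REF)
  alt_list <- VariantAnnotation::alt(vcf)
  alt1 <- vapply(alt_list, function(a) as.character(a)[1], character(1))
  alt2 <- vapply(alt_list, function(a)
    if (length(a) > 1) as.character(a)[2] else NA_character_, character(1))
  g <- VariantAnnotation::geno(vcf)
  gt_raw <- g$GT
  GT <- apply(gt_raw, 2, function(col) {
    col[col %in% c(".", "./.", ".|.")] <- NA
    suppressWarnings(as.integer(sub("[/|].*", "", col)))
  })
  GT <- matrix(GT, nrow = n, dimnames = dimnames(gt_raw))
  DP <- if ("DP" %in% names(g)) matrix(as.integer(g$DP), nrow = n, dimnames = dimnames(g$DP))
        else matrix(NA_integer_, n, length(samples))
  AD_ALT <- matrix(NA_integer_, n, length(samples))
  if ("AD" %in% names(g)) {
    ad <- g$AD
    for (s in seq_along(samples))
      AD_ALT[, s] <- vapply(seq_len(n), function(i) {
        v <- ad[[i, s]]
        if (length(v) >= 2 && !all(is.na(v))) as.integer(v[2]) else NA_integer_
      }, integer(1))
  }
  info <- VariantAnnotation::info(vcf)
  vclass <- if ("VC" %in% names(info)) as.character(info$VC)
            else ifelse(nchar(ref) == 1L & nchar(alt1) == 1L, "SNP", "indel")
  vclass[is.na(vclass)] <- ifelse(nchar(ref) == 1L & nchar(alt1) == 1L,
                                  "SNP", "indel")[is.na(vclass)]
  variant_set(BiocGenerics::start(rr) - 1L, ref, alt1, alt2, vclass,
              GT, DP, AD_ALT, samples = samples)
}
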