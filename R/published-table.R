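#' Published per-class variant statistics for the A. thaliana mitogenome
#'
#' Per-functional-class site totals, SNP and indel counts and mean minor
#' allele frequencies from a published population survey of mitochondrial
#' variation across Arabidopsis thaliana accessions, bundled as plain TSV.
#' These counts are the desk-scale inputs for the density-contrast
#' statistics: the synonymous-vs-intergenic chi-square, the
#' genic-vs-intergenic fold ratio and the per-class densities.
#'
#' @return data.frame with columns `class`, `sites`, `snps`,
#'   `snps_per_site`, `snp_maf`, `indels`, `indels_per_site`, `indel_maf`.
#' @examples
#' tab <- population_variant_table()
#' genic_intergenic_fold(tab)
#' syn_vs_intergenic_chisq(tab)
#' @export
population_variant_table <- function() {
  path <- system.file("extdata", "population_variant_table.tsv",
                      package = "mitodyn")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}
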