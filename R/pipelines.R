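## End-to-end pipelines tying the stages together: the population scan
## (filter -> polarize -> partition -> densities -> spectrum -> chi-square)
## and the MA-line scan (depth -> CPMM windows -> composition model -> runs
## test -> divergence scans -> variant screens).  All reports are TSV; every
## run log carries the configuration hash and seed so identical inputs give
## byte-identical outputs.

pipeline_log <- function(out_dir, config, seed) {
  h <- substr(digest_config(config), 1, 12)
  writeLines(c(sprintf("mitodyn %s", as.character(utils::packageVersion("mitodyn"))),
               sprintf("config_hash: %s", h),
               sprintf("seed: %s", format(seed))),
             file.path(out_dir, "run_log.txt"))
  h
}

## stable hash of a configuration list (md5 of its deparsed form)
digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

tsv <- function(df, out_dir, name) {
  write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Population-variation pipeline
#'
#' Filters a multi-sample variant set on coverage, polarizes by
#' minor-allele frequency and (when an outgroup alignment is supplied) by
#' outgroup projection, partitions the genome, and writes the density table,
#' mutation spectrum, polarization report and the synonymous-vs-intergenic
#' chi-square contrast.
#'
#' @param vcf_path multi-sample VCF.
#' @param genome `annotated_genome` (or FASTA + GFF3 paths via
#'   `fasta_path`/`gff_path`).
#' @param out_dir output directory (created if missing).
#' @param outgroup_blocks optional alignment-block data.frame for outgroup
#'   polarization.
#' @param median_coverage genome-wide median coverage used by the filter.
#' @param fasta_path,gff_path alternative genome input as files.
#' @param min_depth,low_mult,high_mult filter thresholds.
#' @param seed integer seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return list with `density`, `spectrum`, `polarization`, `chisq`,
#'   `filtered` (invisible file outputs in `out_dir`).
#' @export
run_population_pipeline <- function(vcf_path, genome = NULL, out_dir,
                                    outgroup_blocks = NULL,
                                    median_coverage = 100,
                                    fasta_path = NULL, gff_path = NULL,
                                    min_depth = 50, low_mult = 0.5,
                                    high_mult = 3, seed = 1L) {
  for (p in c(vcf_path, fasta_path, gff_path))
    if (!is.null(p) && !file.exists(p)) stop("missing input: ", p)
  if (is.null(genome)) {
    if (is.null(fasta_path) || is.null(gff_path))
      stop("supply either 'genome' or both 'fasta_path' and 'gff_path'")
    genome <- annotated_genome(read_genome_fasta(fasta_path),
                               read_features_gff3(gff_path))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log(out_dir, list(vcf = vcf_path, median = median_coverage,
                             min_depth = min_depth, low = low_mult,
                             high = high_mult), seed)
  vs <- read_vcf(vcf_path)
  filtered <- filter_variants(vs, median_coverage, min_depth, low_mult, high_mult)
  partition <- partition_positions(genome)
  pol_maf <- polarize_by_maf(filtered)
  pol_out <- if (!is.null(outgroup_blocks))
    polarize_by_outgroup(filtered, outgroup_blocks) else NULL
  spectrum <- mutation_spectrum(if (is.null(pol_out)) pol_maf else {
    ## prefer outgroup calls, fall back to MAF where unpolarized
    ok <- pol_out[pol_out$method != "unpolarized", ]
    rbind(ok, pol_maf[!pol_maf$site %in% ok$site, ])
  })
  dens <- density_by_class(filtered, partition, genome)
  agreement <- if (!is.null(pol_out)) polarization_agreement(pol_maf, pol_out)
               else list(agreement = NA_real_, n_compared = 0L)
  tsv(dens$table, out_dir, "density_table.tsv")
  spec_df <- data.frame(metric = c("transitions", "transversions",
                                   "at_gaining", "at_losing", "at_neutral",
                                   "at_bias_ratio", "n_polarized"),
                        value = c(spectrum$transitions, spectrum$transversions,
                                  spectrum$at_gaining, spectrum$at_losing,
                                  spectrum$at_neutral, spectrum$at_bias_ratio,
                                  spectrum$n))
  tsv(spec_df, out_dir, "spectrum.tsv")
  tag <- function(df, what) {
    if (nrow(df) == 0)
      return(cbind(method_set = character(0), df))
    cbind(method_set = what, df)
  }
  pol_df <- rbind(tag(pol_maf, "maf"),
                  if (!is.null(pol_out)) tag(pol_out, "outgroup"))
  tsv(pol_df, out_dir, "polarization.tsv")
  chisq <- dens$syn_vs_intergenic_chisq
  tsv(data.frame(test = "synonymous_vs_intergenic",
                 statistic = chisq$statistic, df = chisq$dof, p = chisq$p),
      out_dir, "chisq.tsv")
  invisible(list(density = dens, spectrum = spectrum,
                 polarization = pol_df, agreement = agreement,
                 chisq = chisq, filtered = filtered))
}

#' Mutation-accumulation divergence pipeline
#'
#' From per-sample alignments and a sample sheet (sample, treatment, line):
#' per-position depth, CPMM windows with mtpt/edge exclusions, the
#' nucleotide-composition model, the spatial runs test, the windowed
#' divergence scan on raw CPMM and on residuals, the repeat-pair
#' recombination scan, and (when a variant set is supplied) the unique-line
#' and heteroplasmy screens.
#'
#' @param alignments named list of alignment data.frames (or paths to
#'   SAM/BAM files), names matching the sample sheet.
#' @param samples data.frame with columns `sample`, `treatment`, `line`.
#' @param genome `annotated_genome` (with mtpt intervals and, optionally,
#'   repeat pairs; repeats are discovered when absent).
#' @param out_dir output directory.
#' @param variants optional `variant_set` for the variant screens.
#' @param config [sim_config()] supplying window size and insert model.
#' @param fdr FDR threshold (default 0.05).
#' @param seed integer seed recorded in the run log.
#' @return list with `window_matrix`, `runs`, `scan_raw`, `scan_residual`,
#'   `recombination`, `unique_variants`, `heteroplasmies`.
#' @export
run_ma_pipeline <- function(alignments, samples, genome, out_dir,
                            variants = NULL, config = sim_config(),
                            fdr = 0.05, seed = 1L) {
  stopifnot(all(c("sample", "treatment", "line") %in% names(samples)))
  if (is.null(names(alignments)) || !setequal(names(alignments), samples$sample))
    stop("alignment names do not match the sample sheet")
  if (nrow(samples) < 2L) stop("CNV scan needs a replicated multi-sample design")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log(out_dir, list(samples = samples$sample, fdr = fdr,
                             window = config$window_size), seed)
  alignments <- lapply(alignments, function(a)
    if (is.character(a)) read_alignments(a) else a)
  alignments <- alignments[samples$sample]
  per_sample <- lapply(alignments, function(a)
    cpmm_windows(depth_profile(a, genome$length), genome,
                 window_size = config$window_size))
  wm <- window_matrix(per_sample)
  tsv(cbind(wm$windows, t(wm$cpmm)), out_dir, "window_matrix.tsv")
  runs <- spatial_runs_test(wm)
  tsv(data.frame(n_retained = runs$n_above + runs$n_below,
                 observed_crossings = runs$observed_crossings,
                 expected_crossings = runs$expected_crossings,
                 z = runs$z, p = runs$p_value),
      out_dir, "runs_test.tsv")
  scan_raw <- window_divergence_scan(wm, samples$treatment, samples$line,
                                     response = "raw", fdr = fdr)
  scan_res <- window_divergence_scan(wm, samples$treatment, samples$line,
                                     response = "residual", fdr = fdr)
  tsv(as.data.frame(scan_raw), out_dir, "cnv_scan_raw.tsv")
  tsv(as.data.frame(scan_res), out_dir, "cnv_scan_residual.tsv")
  reps <- genome$repeats
  if (is.null(reps) || !nrow(reps)) reps <- find_repeat_pairs(genome)
  recomb <- NULL
  if (nrow(reps)) {
    fractions <- vapply(samples$sample, function(s) {
      counts <- count_conformations(alignments[[s]], reps,
                                    config$insert_mean, config$insert_sd)
      recombinant_fraction(counts)$fraction
    }, numeric(sum(reps$in_range %||% rep(TRUE, nrow(reps)))))
    fractions <- matrix(fractions, ncol = nrow(samples),
                        dimnames = list(NULL, samples$sample))
    recomb <- recombination_divergence_scan(t(fractions), samples$treatment,
                                            samples$line, fdr = fdr)
    recomb <- cbind(recomb, mean_fraction = rowMeans(fractions, na.rm = TRUE))
    tsv(recomb, out_dir, "recombination_scan.tsv")
  }
  uniq <- het <- NULL
  if (!is.null(variants)) {
    line_map <- setNames(samples$line, samples$sample)
    uniq <- unique_line_variants(variants, line_map)
    het <- heteroplasmic_candidates(variants)
    tsv(uniq, out_dir, "unique_line_variants.tsv")
    tsv(het, out_dir, "heteroplasmy.tsv")
  }
  invisible(list(window_matrix = wm, runs = runs, scan_raw = scan_raw,
                 scan_residual = scan_res, recombination = recomb,
                 unique_variants = uniq, heteroplasmies = het))
}
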