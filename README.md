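# mitodyn

Intraspecific divergence analysis for plant mitochondrial genomes.

Angiosperm mitogenomes accumulate point mutations slowly but are
structurally dynamic: they recombine across repeated sequences and vary in
the copy number of local regions on short generational timescales.  mitodyn
implements, as a tested and reusable R package, the statistical pipeline for
characterising that dynamics from resequencing data:

* **Variant spectrum** — coverage-based filtering of multi-sample VCFs,
  polarization of alleles into ancestral/derived states (outgroup
  projection through gapped alignments, or minor-allele-frequency
  reasoning), directional mutation spectra with AT-gain/AT-loss and
  transition:transversion accounting, and per-functional-class substitution
  density tables with the genic-vs-intergenic contrasts.
* **Genome partition** — every position of an annotated circular mitogenome
  assigned to CDS / tRNA / rRNA / intron / pseudogene / intergenic, with
  fractional synonymous and nonsynonymous site totals from codon
  degeneracy (Nei–Gojobori-style counting).
* **Copy-number scan** — per-position depth, counts per million mapped
  reads (CPMM) averaged in 500-bp windows with mtpt/edge exclusions, a
  nucleotide-composition correction (GC + long homopolymers), a
  Wald–Wolfowitz runs test for spatial coherence, and a nested mixed-model
  treatment/line divergence scan (`y ~ treatment + (1|line)`, Satterthwaite
  p-values, BH-FDR across windows).
* **Repeat recombination** — discovery of 100–500-bp repeat pairs at ≥80 %
  identity by seeded self-comparison, and quantification of recombinant vs
  parental genome conformations from paired-read mapping geometry, with
  Wilson intervals and the same nested divergence scan.
* **ddPCR** — Poisson copy-number quantification from droplet counts and
  one-tailed Welch comparisons.
* **Synthetic data** — a fully seeded generator of annotated toy
  mitogenomes, population variants, copy-number-structured paired-read
  alignments (SAM), recombinant molecules and ddPCR droplets, with complete
  truth records, so the entire pipeline runs and is validated without any
  external dataset.

The core statistic of the divergence scan is, per retained window *w*,

    CPMM_ws = depth_ws · 10⁶ / mapped_s        (sample s)
    CPMM_ws ~ treatment + (1 | line)           (line nested in treatment)

with Benjamini–Hochberg control across windows, run on both raw CPMM and
the residuals of `CPMM ~ GC + homopolymers(>7 bp)`.  Recombinant
conformations at a repeat pair are read pairs linking the left flank of one
copy to the opposite flank of the other (strand-flipped for inverted
repeats), with a junction-implied insert inside the fragment-length window
and a discordant reference-frame insert; the recombinant fraction is
`R / (R + P)`.

## Worked example

Published per-class variant counts ship with the package and reproduce the
headline desk-scale statistics:

```r
library(mitodyn)
tab <- population_variant_table()
syn_vs_intergenic_chisq(tab)     # chi-square = 0.807 (df = 1, p = 0.369)
genic_intergenic_fold(tab)       # 2.92
```

A full in-silico mutation-accumulation experiment — 2 treatments × 3 lines
× 3 replicates over a 20-kb toy mitogenome with six windows shifted +15 %
in the salt treatment:

```r
cfg <- sim_config(genome_length = 20000L, n_mtpt = 1L, n_homopolymers = 10L)
g   <- build_toy_genome(cfg, seed = 1)
ma  <- simulate_ma_design(cfg, seed = 1, genome = g)

per  <- lapply(ma$alignments, function(a)
  cpmm_windows(depth_profile(a, g$length), g))
wm   <- window_matrix(per)
scan <- window_divergence_scan(wm, ma$samples$treatment, ma$samples$line)

scan[scan$significant, c("window", "start", "end", "ratio", "treatment_p_adj")]
#>    window start  end ratio treatment_p_adj
#> 12     13  6000 6500  1.09         0.02217
#> 13     14  6500 7000  1.10         0.00650
#> 14     15  7000 7500  1.14         0.00421
#> 15     16  7500 8000  1.13         0.00171
#> 16     17  8000 8500  1.09         0.03963
#> 17     18  8500 9000  1.12         0.00421
ma$truth$shifted_windows
#> [1] 13 14 15 16 17 18
```

The scan recovers exactly the six planted windows (ratios attenuated
slightly below 1.15 by per-million normalisation — see the methods
vignette).  Adjacent windows deviate coherently from the median:

```r
spatial_runs_test(wm)
#> Wald-Wolfowitz runs test
#>   values: 35 (above 17 / below 17)
#>   crossings: observed 6, expected 17.00 (var 8.24)
#>   z = -3.831, p = 0.0002549 (normal)
```

Repeat pairs and recombinant conformations (the generator plants a 5 %
recombinant fraction by default):

```r
rp <- find_repeat_pairs(g)
cc <- count_conformations(ma$alignments[[1]], rp,
                          cfg$insert_mean, cfg$insert_sd)
recombinant_fraction(cc)
#>   pair parental recombinant informative fraction ci_lo ci_hi
#> 1    1      192          12         204    0.059 0.034 0.100
#> 2    2      293          12         305    0.039 0.023 0.068
```

ddPCR quantification:

```r
d <- simulate_ddpcr(1000, 0.00085, 20000, seed = 1)
ddpcr_poisson_copies(d$n_positive, d$n_total, 0.00085)$copies_per_ul
#> [1] 1000.5
```

Higher-level entry points `run_population_pipeline()` and
`run_ma_pipeline()` chain the stages and write TSV reports with a config
hash and seed; `inst/scripts/mitodyn` wraps them for shell use.

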