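---
title: "Models and methods behind mitodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodyn)
```

## The problem

Angiosperm mitochondrial genomes are large, slow to accumulate point
mutations, and structurally restless: they recombine across repeated
sequences, coexist as populations of alternative conformations within a
single plant, and show heterogeneous sequencing coverage that reflects real
variation in the stoichiometry of genome regions.  mitodyn implements the
statistical machinery for studying this intraspecific dynamics from
resequencing data along three axes:

1. **Sequence variation** — where substitutions and indels sit in the
   genome's functional landscape, which allele is ancestral, and what the
   directional mutation spectrum looks like.
2. **Copy-number variation** — whether 500-bp windows of normalised read
   depth (counts per million mapped reads, CPMM) diverge between
   experimental treatments and propagation lines, beyond what nucleotide
   composition biases of the sequencing process explain.
3. **Structural variation** — how often read pairs spanning short repeat
   pairs support recombinant rather than parental genome conformations.

Every analysis is exercisable end to end on synthetic data with known
truth, so the package needs no external datasets to be validated.

## Variant filtering and polarization

Variant calls enter as a multi-sample VCF.  A per-sample call is kept when
its site depth is at least 50 and within one half to three times the
genome-wide median coverage; these bounds guard against nuclear insertions
of mitochondrial DNA (numts) and repeat mis-mapping, which manifest as
aberrantly low or high local depth.  Both thresholds are arguments of
`filter_variants()`.

Polarization assigns ancestral and derived states by two routes:

* **Outgroup projection** (`polarize_by_outgroup()`): the variant position
  is projected through gapped alignment blocks onto an outgroup genome;
  blocks must be at least 400 bp at 90 percent identity.  When the outgroup
  base equals one observed allele, that allele is ancestral.  Conflicting
  overlapping blocks leave the site unpolarized (conservative, rather than
  majority vote).
* **Allele frequency** (`polarize_by_maf()`): derived alleles are typically
  rare, so the highest-frequency allele is called ancestral.  Exact 50/50
  ties stay unpolarized.  At triallelic sites the major allele is ancestral
  and each other observed allele is counted as its own derived change —
  real population surveys report only a handful of such sites, and this
  rule is a documented choice, not forced by the data.

`polarization_agreement()` measures how often the two routes name the same
derived allele set at doubly-polarized sites.  On synthetic populations
drawn with a neutral 1/k derived-allele frequency spectrum over 24
accessions, the frequency route is wrong whenever the derived allele has
drifted above one half, which happens often enough to put agreement in the
80–90 percent range — the same order as observed in real surveys.

The directional spectrum (`mutation_spectrum()`) tabulates the 4x4
ancestral-by-derived matrix, collapses it to the six strand-symmetric pair
classes, and reports transition:transversion counts and the AT-gain to
AT-loss ratio (substitutions moving G:C pairs to A:T or T:A gain AT;
the reverse lose it; A:T to T:A and G:C to C:G are neutral).

## Functional partition and site counting

`partition_positions()` assigns every genome position exactly one class,
with overlaps resolved by the precedence CDS > tRNA > rRNA > intron >
pseudogene > intergenic — the most functionally constrained class wins; the
order is configurable because annotations rarely justify a unique choice.
Coordinates are 0-based half-open internally; GFF3, VCF and SAM are
converted at the I/O boundary only.

Synonymous and nonsynonymous site totals are fractional, in the
Nei–Gojobori style: each codon position contributes the fraction of its
three possible single-base changes that preserve the amino acid.  This
accounts for two- and three-member codon families where degeneracy is
partial.  Mutations creating stop codons count as nonsynonymous; the
terminal stop codon is excluded before counting.  Tools differ in these
conventions, so exact equality with any particular site-counting program is
not claimed; the invariant that is enforced (and tested against exhaustive
9-mutation enumeration) is internal consistency: `syn + nonsyn = 3 x
codons`.

Variant effects in coding sequence are classified by translating the
reference and alternate codons on the coding strand, with codons assembled
across introns from the CDS parts in annotation order and
reverse-complemented for minus-strand genes.

## The copy-number scan

Depth at each position counts mapped, non-duplicate alignment records
whose CIGAR reference span covers it.  CPMM is `depth x 1e6 / mapped
records`, averaged in non-overlapping 500-bp windows.  Three classes of
windows are excluded: windows overlapping a plastid-derived insertion
(mtpt) by at least one base (cross-mapping of abundant plastid reads),
the first and last windows (artifacts of linearising a circular map), and
any trailing partial window (same edge concern).  Windows are fixed to the
reference frame; circularity is handled by the edge exclusion rather than
wrap-around windows.

Because amplification-based sequencing is biased by local base
composition, window CPMM is regressed on GC fraction and the count of
homopolymers longer than 7 bp (a run belongs to the window containing its
first base).  The scan runs both on raw CPMM and on the residuals of this
model, fitted per sample; results are labelled by response.

Spatial coherence is tested with a Wald–Wolfowitz runs test on retained
windows in genomic order, centred at their median: adjacent windows
deviating in the same direction produce fewer median crossings than the
null expectation `2 n1 n2 / (n1 + n2)`.  Values equal to the centre are
dropped before counting, following the common convention.  The normal
approximation applies a continuity correction of 0.5 to the discrete
crossing count — without it the approximation misses the exact permutation
p-value by up to 0.3 at small window counts, with it by at most about 0.04
for balanced splits at n of 10 or less; an exhaustive-enumeration mode
(`exact = TRUE`) is available up to n = 12.  At the scale of real scans
(several hundred windows) the correction is immaterial.

Per window, divergence between treatments is tested with a linear mixed
model, `response ~ treatment + (1 | line)`, with lines uniquely labelled so
the random intercept is implicitly nested in treatment.  The default
p-value uses the Satterthwaite denominator-degrees-of-freedom
approximation (lmerTest); a likelihood-ratio option exists.  When the line
variance component is estimated at zero the mixed fit is singular and the
function falls back to the classical balanced nested ANOVA, testing
treatment over the line-within-treatment stratum; the `method` field
records which path produced each p-value.  Benjamini–Hochberg adjustment
is applied across windows separately per effect and response.

One subtlety worth knowing: per-million normalisation couples windows.  If
a fraction *f* of the genome is amplified by a factor *s* in one
treatment, every other window's CPMM is deflated by roughly `1 + f (s - 1)`
in that treatment, so the observed window ratio understates the molecular
shift by that factor.  This is inherent to relative-abundance data, not an
artifact of the implementation; it is why the synthetic defaults keep the
shifted fraction of the genome small (about 6 percent), as in real scans
where significant windows are a few percent of the genome.

## Repeat pairs and recombinant conformations

`find_repeat_pairs()` self-compares the genome (both orientations) by
exact 12-mer seeding, clusters seeds on shared diagonals, extends gaplessly
with an X-drop rule, and trims to the maximal-identity span; identity is
computed over the full aligned span.  Pairs between 100 and 500 bp at 80
percent identity or better are in scan range; longer or shorter pairs are
reported but flagged out of range.  The circular origin is handled by
scanning the sequence extended by the maximum repeat length and reducing
coordinates modulo the genome length.  Seeding with exact 12-mers bounds
sensitivity: at 80 percent identity the chance that a 100-bp repeat
contains no exact 12-mer is below a percent, but heavily diverged repeats
just above the threshold can in principle be missed; planted-truth tests
cover the 80–100 percent range used in practice.

A read pair is classified against a repeat pair by flank anchoring.  Label
the flanks L1/R1 and L2/R2.  A forward mate anchored in L1 (it starts in
the flank window before copy 1, and may read into the repeat) with its
reverse mate anchored in R1 and a reference-frame insert within
`mean ± 4 SD` is parental for copy 1.  A pair linking L1 to R2 (or L2 to
R1) with forward/reverse orientation, a *junction-implied* insert inside
the same window, and a reference-frame insert outside it (the pair must be
discordant on the reference — otherwise an ordinary fragment between two
nearby copies would mimic a junction) is recombinant for a direct repeat.
For inverted repeats the crossover flips the downstream segment, so
junction-spanning mates map to the same reference strand: L1+L2 both
forward, or R1+R2 both reverse.  Mates lying wholly inside a repeat copy
are never used (multi-mapping ambiguity), and pairs satisfying more than
one hypothesis are uninformative.  An earlier, stricter rule — mates wholly
inside the flanks — was rejected because with a 245-bp insert and 150-bp
reads it makes even 150-bp repeats unspannable; anchoring reproduces what
spanning-pair counting can actually observe.

Recombinant fractions are `recombinant / (recombinant + parental)` with a
Wilson score interval, and the treatment/line divergence scan over repeat
pairs reuses the nested mixed model with BH adjustment.

## ddPCR quantification

Droplet digital PCR partitions template into ~20,000 droplets of 0.85 nl;
per-droplet copies are Poisson, so the concentration follows from the
fraction of negative droplets: `lambda = -ln(1 - n_pos / n_total)` copies
per droplet, divided by droplet volume for copies per microlitre.  The
estimate diverges as droplets saturate; `ddpcr_poisson_copies()` raises an
error at 100 percent positives rather than returning infinity.  High- vs
low-coverage regions are compared with one-tailed Welch t-tests
(`one_tailed_t()`); Welch rather than pooled-variance because equal
variances between primer sets has nothing to recommend it and costs little
when true.

## The synthetic-data generator

`sim_config()` centralises the generator's parameters.  The defaults are
the package's reference study conditions, chosen once:

* **Genome**: 50 kb circular, 45 percent GC, with functional-class
  proportions matching a real crucifer mitogenome scaled down (8.5 percent
  protein-coding, 1.4 rRNA, 0.5 tRNA, 0.3 pseudogene, 9.6 intron, the rest
  intergenic).  Genes are generated in frame without internal stops, some
  on the minus strand, some split by an intron.  Two direct repeat pairs
  (150 bp, 85 percent identity — inside the scan range and spannable by the
  insert model), two 1-kb mtpt intervals and 30 long homopolymers are
  planted in intergenic gaps.
* **Population variants**: per-class SNP and indel rates equal to the
  observed per-site densities of a published Arabidopsis population survey
  (e.g. 0.0034 SNPs per intergenic site); indels only in introns and
  intergenic sequence, as observed.  Derived alleles are drawn from a
  directional spectrum whose expected AT-gain:AT-loss ratio equals the
  configured `at_bias = 7`, solved against the realised base composition of
  the sampled sites so the emitted truth tally is unbiased; the
  transition fraction default of 0.4 matches the observed 422:686.
  Derived-allele counts across 24 accessions follow the neutral 1/k
  spectrum.
* **MA design**: 2 treatments x 3 lines x 3 replicates, as in real
  mutation-accumulation sequencing.  All samples share a smooth baseline
  profile (circular moving-average log-normal noise) that gives the
  spatially coherent coverage heterogeneity real libraries show; a
  contiguous block of 6 windows (about 6 percent of the default genome,
  matching the sparse treatment effects of real scans) is shifted 15
  percent in the salt treatment; lines add 1 percent window-level
  log-normal noise.
* **Read model**: 2x150 bp pairs, insert 245 ± 50 bp, 500x depth.  The
  insert matches real mitochondrial library preps; the depth reflects that
  mitogenome coverage in total-DNA or enriched libraries runs to hundreds
  or thousands-fold, and is the noise level at which treatment shifts of
  the observed magnitude (15–20 percent) are statistically detectable with
  this small design — as they were in the real experiment.  Alignments are
  emitted directly with correct coordinates, flags, mate fields and insert
  sizes, so no external aligner is needed; `write_fastq_pair()` exists for
  users who want to run one.  Sequencing error is off by default (variant
  calling is out of scope); optional duplicate injection exercises the
  duplicate filter.
* **Recombinants**: fragments fully spanning a repeat copy are re-drawn
  from the recombined conformation with the configured probability and
  their distal mates mapped back through the junction — exactly the
  geometry the classifier detects, so planted fractions are recovered
  without bias.  The generator plants direct-repeat recombinants;
  inverted-repeat geometry is covered by constructed test cases.
* **ddPCR**: 1000 copies per microlitre in 20,000 droplets of 0.85 nl.

Everything is deterministic given `(config, seed)`; seeds for sub-stages
are derived from the master seed, and the session RNG state is restored
after every call.

`simulate_window_profiles()` generates the MA design directly at the
window level — same layout, with window noise matched analytically to the
read model (the CV of a window mean at depth *d* is
`1 / sqrt(d (window + insert) / (2 read_length))`, which reproduces the
empirical CV of the read-level simulator within about 10 percent) and
per-sample per-million renormalisation.  Many-seed power and calibration
studies use it because full read simulation adds nothing to those
questions; read-level round trips are tested separately at fewer seeds.

### What the generator does not emulate

Sequencing error and base-quality structure, chimeric reads, mappability
variation, plastid/nuclear contamination and bacterial co-enrichment,
heteroplasmy drift across generations, and gene conversion between repeat
copies.  Passing recovery tests therefore shows the statistical machinery
is correct under the stated noise model, not that a real pipeline's
upstream artifacts are handled; the coverage filters and mtpt/edge
exclusions are the package's defences against the most important of those
artifacts, and they are exercised structurally rather than by emulating
the artifacts themselves.

## Numerical and testing choices

* Problem sizes in the test-suite: parameter-recovery checks run at a
  12–50 kb genome; the window-scan sensitivity check uses 50-window
  profiles over 100 seeds (about 600 mixed-model fits per seed-set), the
  null-calibration checks 600 model fits and 30-seed all-null scans; the
  spectrum check pools about 1300 SNPs.  These sizes give the binomial
  intervals quoted in each test while keeping the suite fast.
* The 2x2 chi-square uses no continuity correction; with Yates' correction
  the published synonymous-vs-intergenic contrast (counts 19/6922 vs
  987/292055) gives about 0.6 instead of the printed 0.8.
* BH adjustment, Welch t, OLS, the mixed model and chi-square are the
  stock R implementations (`p.adjust`, `t.test`, `lm`, `lmerTest::lmer`,
  `chisq.test`); tests verify each against an independent closed form or
  exhaustive oracle rather than re-implementing them.
* Degenerate inputs are first-class: constant responses return
  non-significant degenerate results; all-N windows flag GC as undefined;
  zero informative read pairs flag fractions as undefined; saturated ddPCR
  errors; zero-variance correlations warn and return NA.

## Known limitations

* Repeat discovery is seeded with exact k-mers; repeats barely above the
  80 percent identity floor can be missed (bounded above).
* Origin-spanning repeat copies keep unwrapped coordinates (end past the
  genome length); downstream read-pair classification treats the map as
  linear, consistent with the edge-window exclusions.
* The MAF route mis-polarizes high-frequency derived alleles by
  construction; spectrum estimates from MAF-polarized data are attenuated
  toward 1 relative to outgroup-polarized data, which is why the agreement
  statistic is reported alongside.
* `nested_treatment_model()` expects the balanced replicated design it was
  built for; heavily unbalanced designs will run through lmer but the
  nested-ANOVA fallback assumes balance.
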