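Package: mitodyn
Title: Intraspecific Plant Mitogenome Divergence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing short-term divergence of plant mitochondrial
    genomes from resequencing data: coverage-based variant filtering, mutation
    spectrum polarization by outgroup projection or minor-allele frequency,
    functional partitioning of an annotated circular mitogenome with fractional
    synonymous/nonsynonymous site counting, windowed copy-number scans on
    depth normalised as counts per million mapped reads (CPMM) with nucleotide
    composition correction and nested mixed-model treatment tests, detection
    and quantification of repeat-mediated recombinant genome conformations
    from paired-read mapping geometry, and droplet digital PCR (ddPCR) Poisson
    copy-number estimation.  A seeded simulator of annotated toy mitogenomes,
    population variants, copy-number-structured paired reads and ddPCR
    droplets makes the whole pipeline exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    VariantAnnotation,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
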