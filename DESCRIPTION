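Package: teSpread
Title: Heterochromatin Spreading Analysis Around Transposable Element Families
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the spreading of repressive chromatin (DNA
    methylation, H3K9me2) from retrotransposon families into flanking
    low-copy DNA. Provides distance-binned enrichment profiling of
    single-copy array probes around annotated repeats, a permutation-based
    classifier of spreading families against randomly placed
    pseudo-insertions, bisulfite sequence-context (CG/CHG/CHH) methylation
    summaries of low-copy flanks, detection of polymorphic insertions
    (empty sites) from whole-genome alignments with cross-genotype
    differential methylation at the nearest probe, distance-stratified
    analysis of gene expression near repeats, family attribute
    characterization, and a self-consistent synthetic data generator with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
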