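Package: hmcompare
Title: Comparative Analysis of Affinity-Based 5-Hydroxymethylcytosine
    Enrichment Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative analysis of affinity-based
    5-hydroxymethylcytosine (5hmC) enrichment techniques on tiling-array
    data. Provides a synthetic-epigenome generator with technique-specific
    transfer functions (antibody, chemical capture and protein-affinity
    enrichment), loess and scale normalisation of log2(IP/input) probe
    signals, percentile sliding-window peak calling, five-way genomic
    annotation of probes, sample correlation clustering and autocorrelation
    diagnostics, length-normalised metagene and midpoint-window profiles,
    detection of technique-biased regions with repeat-class rank tests,
    CpG observed/expected composition, chromatin-state overlap scoring,
    and quantification of 5hmC/5mC/C fractions from glucosyl-sensitive
    restriction-enzyme qPCR (gRES-qPCR) cycle-threshold tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    limma,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
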