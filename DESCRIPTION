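Package: relicdx
Title: Ancient-DNA Authentication and Clinical Exome Variant Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for running a clinical-exome analysis on highly degraded
    (ancient) DNA: cytosine-deamination damage profiling and fragment-length
    summaries for data authentication, Ry-statistic molecular sex
    determination, likelihood-based mitochondrial and X-chromosome
    contamination estimation, exome capture quality-control metrics
    (duplication, coverage, genotypability, FOLD80), a two-arm clinical
    variant prioritization cascade over ClinVar/HGMD annotations and
    population frequencies, and cis/trans phase inference for a variant
    absent from a phased reference haplotype panel via anchor-carrier
    linkage-disequilibrium block discovery. Includes seeded synthetic-data
    generators (damaged read sets, pileups, annotated variant tables,
    founder-mosaic haplotype panels) with ground-truth bookkeeping so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    vcfR,
    jsonlite,
    graphics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
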