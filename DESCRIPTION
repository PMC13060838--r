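Package: crecascade
Title: CRISPRi Screen Analysis for CRE-Gene Mapping and Regulatory Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled CRISPRi screens with single-cell
    readout in primary CD4+ T cells: synthetic screen simulation with
    negative-binomial counts and a planted regulatory ground truth, cell and
    gRNA quality control, pseudobulk negative-binomial differential
    expression with BH false-discovery control, classification of
    CRE-to-gene links into genomic-context interaction classes, enhancer
    prioritization using proximal-mediation filtering together with Hi-C
    contact and TAD co-localization evidence, eQTL and transcription-factor
    target enrichment statistics, and hop-wise propagation of CRE effects
    through a genome-wide perturbation network with per-disease program
    enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
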