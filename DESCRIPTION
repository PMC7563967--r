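Package: miTRAPseq
Title: miRNA Prioritization from miTRAP Pull-Down Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of miTRAP (miRNA trapping by RNA in vitro affinity
    purification) small RNA sequencing experiments, in which an MS2-tagged
    bait 3'UTR pulls down the microRNAs that bind it. Provides tpm
    quantification of eluate/control/input count tables with multi-locus
    aggregation, enrichment ratios of a target bait over the MS2 control
    bait, consensus voting over target-prediction tools, a nearest-neighbor
    dynamic program for miR:UTR duplex minimum free energy with seed-match
    scanning, delta-Ct/delta-delta-Ct qPCR arithmetic including miTRAP
    ratios, a multi-criteria candidate filter with ranked and audited
    reports, downstream validation arithmetic (dual-luciferase
    normalization, densitometry, degranulation, IHC scoring, group tests),
    and a synthetic-data generator with planted ground truth so the whole
    pipeline can be exercised and calibrated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'nn-params.R'
    'duplex.R'
    'enrichment.R'
    'prediction.R'
    'qpcr.R'
    'quantify.R'
    'selection.R'
    'sites.R'
    'simulate.R'
    'validation.R'
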