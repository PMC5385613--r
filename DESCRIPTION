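Package: methwave
Title: Bidirectional DNA Methylation Dynamics in Gametes and
    Pre-Implantation Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of whole-genome bisulfite sequencing
    methylomes across gametes and pre-implantation embryo stages.
    Implements binomial methylated-cytosine calling calibrated against an
    unmethylated lambda spike-in, pairwise sliding-window differentially
    methylated region (DMR) detection with exact Fisher testing,
    SNP-based parent-of-origin methylation tracking with relative
    demethylation level (RDL) classification of actively demethylated
    sites, CpG-island detection and annotation summaries, and a
    synthetic-data generator that emulates a seven-stage embryonic
    methylome with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
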