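Package: pioneerscan
Title: Dissecting Transcription-Factor Binding-Site Selection from Motif,
    Accessibility and Binding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for studying how an ectopically induced
    transcription factor selects its genomic binding sites. Provides
    genome-wide position-weight-matrix scanning with mappability, blacklist
    and signal-based motif filters; a documented Poisson/Benjamini-Hochberg
    stand-in peak caller with factor and region modes; Tn5 cut-site
    processing, accessibility clustering with a per-peak remodeling index and
    single-base footprint profiles; homotypic motif-pair spacing enrichment
    and per-peak motif-class co-occurrence networks; regulatory-domain
    peak-to-gene assignment with an eQTL fallback; logistic bound-versus-
    unbound motif prediction compared by ROC/AUC; and a fully seeded
    synthetic-data generator that emulates a two-condition (induced versus
    control) ChIP/ATAC/RNA experiment with exported ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
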