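Package: atacarray
Title: Chromatin Accessibility Prognostics from ATAC-seq Peak Atlases and
    ATAC-array Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for prognostic analysis of tumor
    chromatin accessibility. Builds a cross-patient atlas of ATAC-seq peaks
    by an overlap-fraction merge heuristic, calls a differential
    accessibility signature between recurrent and non-recurrent patients
    with a multi-factor negative-binomial generalized linear model, relates
    the signature to transcription-factor motifs by ridge regression of
    per-peak log2 fold changes on binary motif presence, computes
    two-channel microarray (ATAC-array) Prognosis Scores from probe-class
    median intensities, and stratifies patients by Kaplan-Meier estimation,
    weighted log-rank tests and hazard ratios. A synthetic-cohort generator
    with planted ground truth makes every stage testable without
    controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    survival,
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
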