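Package: cofactorScope
Title: Transcription-Factor Cofactor Discovery from Motif Modules
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers cofactors of an anchor transcription factor (such as
    HIF1A) from per-cell-line motif modules derived from ChIP-seq peaks.
    Provides position weight matrix alignment with empirical E-value
    calibration and top-k matching against a known-motif library,
    cross-cell-line motif and motif-pair conservation with a
    random-motif-module resampling null, hypergeometric enrichment of
    predicted cofactor pairs against known protein-protein interactions,
    cofactor ranking and recovery statistics, peak extension and
    nearest-TSS target-gene assignment, GO over-representation and a
    pathway-divergence regression, plus a synthetic-study generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomeInfoDb
Config/testthat/edition: 3
RoxygenNote: 7.3.3
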