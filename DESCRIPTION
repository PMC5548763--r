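Package: tcregnet
Title: Time-Course Regulatory Network Analysis of Two-Condition Expression Data
Version: 1.0.0
Authors@R:
    person("Sam", "Whitfield", email = "sam.whitfield@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-condition (control vs. treatment)
    time-course expression studies of genes and miRNAs: within-array median
    scaling, probe filtering, between-sample quantile normalization and
    probe-to-gene collapse; per-timepoint differential-expression calling by a
    mean plus/minus two standard deviation fold-change rule with
    first-emergence (New+/Old+) classification; cross-condition Pearson
    correlation transition profiling; transcription-factor co-expression
    network construction (PCC threshold) partitioned by iterated bridge
    bisection; miRNA-to-TF suppression inference; an integrated signed
    TF-miRNA-gene regulatory network with per-timepoint hub ranking; and
    generic hypergeometric over-representation analysis with
    Benjamini-Hochberg FDR control. Includes a synthetic-data generator with
    serialized ground truth so the full pipeline is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
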