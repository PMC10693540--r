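Package: etcsig
Title: Transcriptional Signature Analysis of Electron Transport Chain Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for targeted RNA-seq (TempO-Seq style)
    count analysis of mitochondrial toxicant exposures in renal cells:
    negative-binomial Wald differential expression with pairwise and
    batch-aware class designs, probe-panel harmonization, class
    intersection and fold-change concordance analysis, hypergeometric
    Z-score over-representation analysis with permutation p-values,
    upstream-regulator activation z-scores on user-supplied signed
    networks, Williams-trend-prefiltered Exp5 benchmark-dose modelling,
    and Seahorse oxygen-consumption-rate percent-of-control
    normalization with Dunnett lowest-observed-effect levels. A bundled
    synthetic-data generator emulates the assumed statistical structure
    (negative-binomial counts, two batches, Exp5-shaped dose-response,
    three inhibitor classes sharing a common signature) so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    minpack.lm,
    multcomp,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
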