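Package: reosig
Title: Qualitative Transcriptional Signatures from Relative Expression Orderings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and application of rank-based (relative expression
    ordering, REO) transcriptional signatures. Identifies gene pairs whose
    within-sample ordering is stable within a phenotype and reversed between
    phenotypes, intersects them across measurement platforms into a reversal
    signature, scores individual samples by the fraction of signature pairs
    showing the disease-characteristic ordering, and provides stage
    correlation of signature pairs, hypergeometric enrichment, and two-group
    differential-expression / treatment-reversal frequency analysis. Includes
    a seeded synthetic-cohort generator with planted reversal pairs, multiple
    platforms, and strictly monotone per-sample batch distortions so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    fgsea,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
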