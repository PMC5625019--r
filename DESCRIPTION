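Package: tftensor
Title: Transcription Factor Interaction Networks by Bayesian Tensor Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates heterogeneous evidence of transcription factor (TF)
    combinatorial interactions in a network paradigm. Weighted TF-TF networks
    are built from ChIP-seq style co-binding (placement-null overlap
    p-values), expression or promoter-methylation profile correlations, and
    regulatory co-occupancy (Jaccard index over occupied promoters), then
    percentile-normalized and stacked into an incomplete noisy 3-way tensor.
    A variational Bayesian CANDECOMP/PARAFAC factorization with
    sparsity-inducing Gamma hyperpriors determines the effective rank
    automatically, completes missing entries, and its factors are fused into
    one precise weighted TF interaction network. Downstream tools call
    strongly relevant interactions (interquartile-range rule), hub TFs, and
    lineage-specific versus housekeeping edges, and score predictions by
    ROC/AUC against network-averaging gold standards. Synthetic-data
    generators emulate every input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
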