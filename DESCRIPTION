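Package: ibctx
Title: Comparative Transcriptomics of Inflammatory Breast Cancer Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative transcriptional analysis of inflammatory
    (IBC) versus non-inflammatory (nIBC) breast cancer preclinical models and
    patient cohorts. Provides batch-robust merging of multi-batch expression
    compendia (expression filtering, empirical-Bayes batch correction,
    quantile normalization, probe collapsing, replicate averaging),
    unsupervised clustering with validity-index voting and annotation
    association tests, an elastic-net transcriptomic IBC classifier with
    replicate-median calling, moderated-t and percentile-based differential
    expression, signed weighted co-expression network analysis (biweight
    midcorrelation, soft thresholding, topological overlap, module detection,
    eigengenes, module preservation), minimum-spanning-tree module
    prioritization, connectivity-map style regulator and drug screening,
    gene-set enrichment and single-sample activity scoring, and the nested
    ER-by-phenotype interaction regression for MYC expression and activity.
    Synthetic-data generators emulate the statistical structure of the study
    designs so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    glmnet,
    igraph,
    limma,
    nnet,
    stats,
    utils,
    withr
Suggests:
    fgsea,
    sva,
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
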