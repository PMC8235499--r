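Package: coderegmiR
Title: Cross-Series miRNA Meta-Analysis and Co-Deregulation Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates heterogeneous miRNA microarray series into a single
    sparse hyper-matrix with explicit block missingness, preprocesses it
    (multiplicative background correction, non-positive masking, quantile /
    loess / rank-invariant normalization, global-mean rescaling, replicate
    averaging), computes per-miRNA tumor-versus-control differential
    expression with Benjamini-Hochberg false discovery control, clusters
    expression profiles (k-means with Calinski-Harabasz model selection,
    hierarchical sub-clustering, descriptive group-mean clustering), scans
    for miRNAs co-deregulated across (nearly) all tumor samples with
    frequency bands, summarises expression by chromosome and cytoband, and
    evaluates candidate markers by ROC analysis and cross-validated naive
    Bayes classification. A multi-series synthetic-data generator with
    planted signatures makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
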