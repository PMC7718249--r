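Package: maceclass
Title: Differential Expression and Centroid Classification for 3' RNA-seq
    of Conjunctival Tumors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for 3' tag RNA sequencing (MACE) of
    conjunctival squamous cell carcinoma, conjunctival papilloma and
    healthy conjunctiva. Provides a negative-binomial count simulator with
    planted group markers, preprocessing (group-wise zero-mean gene
    filtering, median-of-ratios size factors, TPM, linear-model batch
    removal, PCA), a negative-binomial Wald differential-expression stage
    with Benjamini-Hochberg adjustment and strict DEG thresholds,
    marker-panel selection by overlap of pairwise upregulated sets, and a
    30-gene nearest-centroid classifier scored by leave-one-out Pearson
    correlation and diagonal-distance scores, with confusion-matrix,
    sensitivity/specificity and one-vs-rest AUC evaluation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
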