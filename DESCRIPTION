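Package: acupairs
Title: Association Mining Between Diagnosis Patterns and Acupoint Prescriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing prescription records that pair a traditional
    Korean-medicine diagnosis pattern (ICD-10 U/R codes) with a set of WHO
    standard acupoints. Provides a controlled-vocabulary registry and
    normalizer for acupoint and diagnosis codes, a seeded generator of
    virtual-diagnosis cohorts, preprocessing of raw records into validated
    diagnosis-acupoint pair lists, co-occurrence contingency matrices and
    thresholded bipartite networks with eigenvector centrality, tf-idf
    association weights with acupoints as terms and diagnosis patterns as
    documents, a marginal-preserving permutation test of tf-idf significance,
    and a one-command pipeline that emits Gephi-compatible network files and
    tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
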