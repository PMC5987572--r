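Package: ocregnet
Title: One-Class SVM Inference of Transcription-Factor Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts transcription-factor (TF) to target-gene regulatory
    relationships by combining promoter motif evidence with co-expression
    evidence in a one-class support vector machine trained on curated
    TF-target relations only. Promoters are scanned with position weight
    matrices calibrated by an exact dynamic-programming score p-value,
    hits are binned into strand-by-distance windows around the
    transcription start site, and each TF-candidate pair is further
    described by the candidate's correlation with the TF, with the TF's
    protein-interaction neighborhood, and with a background gene panel.
    Downstream tools identify core deregulated TFs in tumor/normal
    expression datasets, cluster TFs into modules by target-set overlap
    (Fisher's exact test), and test Gene Ontology enrichment of
    deregulated targets with specific-term-priority pruning. A synthetic
    data generator plants a known network, co-expression structure and
    deregulated TF modules so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    limma,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
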