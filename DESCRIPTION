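Package: pssmclass
Title: Protein Structural Class Prediction from Segmented PSSM Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts SCOP structural classes (all-alpha, all-beta,
    alpha/beta, alpha+beta) of protein domains from PSI-BLAST
    position-specific scoring matrices. Builds a 700-dimensional feature
    vector per protein by fusing consensus-sequence composition features
    with pseudo-PSSM correlation factors and autocovariance
    transformations computed on two- and three-way segmentations of the
    sigmoid-normalised profile, reduces it by principal component
    analysis, and classifies with one-vs-all radial-basis-function
    support vector machines. Includes jackknife (leave-one-out)
    evaluation with per-class sensitivity, specificity, F-measure,
    Matthews correlation, closed-form AUC, overall and average accuracy,
    a synthetic profile generator for end-to-end validation, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    optparse,
    rlang,
    stats,
    tools,
    utils,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
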