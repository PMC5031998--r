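Package: eemscreen
Title: Excitation-Emission Matrix Fingerprinting for In Vitro Skin-Irritancy Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cell-based fluorescence irritancy assays.
    Paired excitation-emission matrix (EEM) images recorded with and without
    growing keratinocytes are embedded in cross-correlation space, reduced by
    principal component analysis with Kaiser or broken-stick component
    selection, and classified as irritant or non-irritant with a family of
    classifiers (Fisher discriminant with a sensitivity-plus-specificity
    maximizing threshold, weighted kernel k-nearest-neighbours, logistic
    regression, naive Bayes, Gaussian mixtures, kernel density classifiers
    and decision trees). Includes leave-one-out and stratified hold-out
    evaluation protocols, a synthetic five-dye EEM generator for
    benchmarking, and a plain-text dataset interchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    mclust,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Classification, DimensionReduction, Software
RoxygenNote: 7.3.3
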