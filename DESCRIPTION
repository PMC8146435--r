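Package: nitrospec
Title: Hyperspectral Classification of Leaf Nitrogen Status with
    Metaheuristic Wavelength Selection and Majority Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Workflow for classifying plant leaves into nitrogen-treatment
    classes from visible/near-infrared reflectance spectra. Provides a
    synthetic spectra generator with a controlled class-confusability
    structure, chemometric preprocessing (absorbance conversion,
    multiplicative scatter correction, median smoothing), three population
    metaheuristics (biogeography-based optimization, imperialist
    competitive algorithm, harmony search), feed-forward and radial basis
    function neural networks, metaheuristic wavelength selection, five
    classifiers under a uniform fit/predict contract, majority-voting
    ensembling, and an evaluation suite (pooled confusion matrices,
    per-class metrics, ROC/AUC, repeated-split protocol, paired t test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
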