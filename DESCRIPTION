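Package: roiharmony
Title: Harmonization of Multi-Scanner Brain Morphometry Tables
Version: 0.1.0
Authors@R: person("roiharmony", "maintainers", email = "maintainers@roiharmony.org", role = c("aut", "cre"))
Description: Removes scanner-related bias from subject-by-region tables of
    brain volumes measured on different MRI scanners. Provides empirical-Bayes
    ComBat harmonization with covariate control and a stepwise multi-covariate
    scheme (sex, age, scanner), quality-control filters for multi-site cohorts
    (age window, quality-probability cutoffs, iterative per-scanner outlier
    removal, minimum scanner size), Kolmogorov-Smirnov assessment of
    harmonization efficacy, and a machine-learning harmonizer that maps
    per-image quality metrics to the per-region corrections ComBat prescribes,
    so that single images from scanners never seen during fitting can be
    harmonized without a statistically representative sample. Includes a
    multi-scanner cohort simulator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
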