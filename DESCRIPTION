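Package: cprisk
Title: Combined Probability of Concussion from Head Impact Kinematics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for building and evaluating the combined probability of
    concussion (CP), a multivariate logistic injury risk function that maps
    peak linear and rotational head acceleration to the probability that an
    impact is concussive. Includes the incidence-based underreporting
    correction with Gaussian-copula reassignment of high-magnitude
    sub-concussive impacts, ROC/AUC predictive-capability assessment with
    Hanley-McNeil standard errors and correlated-AUC comparison, synthetic
    head-impact generators matched to published class-conditional moments,
    and a command-line pipeline tying the steps together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    fitdistrplus,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
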