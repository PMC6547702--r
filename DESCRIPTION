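Package: pwascc
Title: Pharmacopeia-Wide Case-Crossover Screening of Dispensed Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for pharmacopoeia-wide association studies (PWAS) of
    dispensed prescription drugs and acute-onset clinical events using the
    case-crossover design. Builds per-patient case/control exposure windows
    from prescription-registry tables, fits L1-penalized conditional
    logistic regression on matched-pair exposure differences, performs
    bootstrap-enhanced LASSO (BOLASSO) drug selection with an unpenalized
    joint refit, intersects selections across countries, and combines
    country-specific log relative risks by inverse-variance fixed-effect
    meta-analysis. A synthetic two-country prescription-registry generator
    with planted triggering effects provides a ground-truth test bed.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    glmnet,
    metafor,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
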