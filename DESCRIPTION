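Package: isogeoloc
Title: Forensic Geolocation from Stable Hydrogen and Oxygen Isotopes in
    Keratinous Tissues
Version: 0.1.0
Authors@R:
    person("Isogeoloc", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for closed-population geographic assignment of
    individuals from stable hydrogen and oxygen isotope ratios measured in
    human hair and toenails.  Provides a data model and CSV input/output for
    per-sample delta values, a packaged drinking-water reference table, a
    synthetic cohort generator parameterized by published per-site summary
    statistics, an ordinary-least-squares tissue/water regression battery,
    group-comparison statistics (MANOVA with univariate follow-ups, Tukey
    post-hoc, Shapiro-Wilk gated paired tests, Mahalanobis bivariate outlier
    screening), a from-scratch Gini-impurity CART classifier with text and
    JSON tree rendering, and holdout evaluation via per-class confusion
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
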