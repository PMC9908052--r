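Package: duoMR
Title: Mendelian Randomization of Maternal Exposures on Offspring Outcomes
    Using Mother-Offspring Duos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization of maternal
    exposures on offspring outcomes when the fetal genome threatens the
    exclusion restriction. Implements GWAS summary-statistic harmonization
    and LD-proxy substitution, weighted standardized genetic scores with
    instrument-strength diagnostics (per-SNP variance explained, mean F,
    Cochran's Q), partitioning of own- and offspring-birthweight GWAS
    effects into maternal- and fetal-specific effects via the structural
    weighted-linear-model equations, pleiotropy-robust estimators
    (inverse-variance weighted, MR-Egger, weighted and penalized weighted
    median, leave-one-out), one-sample two-stage least squares with a
    genetic-score instrument, a product-of-paths mediation expectation,
    and a mother-offspring duo cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
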