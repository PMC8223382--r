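Package: ineqdecomp
Title: Decomposition of Educational Inequality in a Binary Child-Health Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies and decomposes group inequality in a binary
    child-health outcome (under-five diarrhoea) between children of
    illiterate and literate mothers across survey-structured data.
    Implements the nonlinear Fairlie extension of the Blinder-Oaxaca
    decomposition for logit models with sequential covariate replacement,
    random orderings, matched subsampling and sampling weights; weighted
    logistic regression by iteratively reweighted least squares with Wald
    and likelihood-ratio fit diagnostics; country-level risk differences
    and odds ratios with fixed- and random-effects (DerSimonian-Laird)
    meta-analysis, I-squared, Mantel-Haenszel pooled odds ratios and
    homogeneity tests; a PCA-based neighbourhood socio-economic quintile;
    and a synthetic generator for clustered, weighted survey data with
    known generative truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
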