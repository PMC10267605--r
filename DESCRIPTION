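Package: indirectRI
Title: Indirect Reference Interval Estimation from Mixed Laboratory Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates and verifies clinical reference intervals from mixed
    hospital laboratory data using three indirect methods: a computerised
    Hoffman cumulative-probability-plot regression, truncated
    Box-Cox-Gaussian fitting with Kolmogorov-Smirnov distance minimisation,
    and inverse modelling via a multi-level grid search with bootstrap
    confidence intervals. Includes a synthetic laboratory-data generator
    with known ground-truth intervals for validating the estimators, CSV
    import of laboratory information system exports, and a verification
    report comparing estimated intervals against manufacturer (kit insert)
    reference ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
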