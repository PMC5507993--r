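Package: passnet
Title: Passing-Network Predictors of Offensive Play Success in Football
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse directed ball-passing networks in association
    football and relate their structure to the outcome of offensive plays.
    Segments match event logs into offensive plays, categorises them as
    successful, unsuccessful or neutral, aggregates them into per-period
    per-team passing networks, computes network density, average local
    clustering and Freeman degree centralization, and fits a two-block
    hierarchical binary logistic regression (total passes, then network
    metrics) with collinearity, linearity-of-the-logit and outlier
    screening, Hosmer-Lemeshow and Nagelkerke diagnostics, and a
    classification table. Includes a synthetic match simulator with a
    ground-truth channel for validating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
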