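Package: iskappa
Title: In Silico Kappa and Control Charts for Interpretive Rate Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring interpretive variation among raters from
    observational sign-out data, motivated by histologic grading of invasive
    breast carcinoma. Computes pathologist interpretive rates (PIRs) per
    score level of the Nottingham grade and its components, volume-normalized
    rates anchored to the group median interpretive rate (GMIR), funnel-plot
    and control-chart outlier classification with nested binomial control
    limits, and the in silico kappa (ISK): an agreement statistic derived
    from marginal interpretive rates alone under either the maximal
    categorical overlap assumption (MCOA, a pairwise kappa-maximum) or the
    ordered mutually exclusive category assumption (OMECA, a cumulative
    category-overlap kappa). Includes parametric-bootstrap confidence
    intervals, a seeded synthetic cohort generator for validation, and a
    command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
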