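Package: dwkit
Title: Disability-Weight Estimation from Paired-Comparison and Population
    Health Equivalence Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring disability weights (DWs) for health states
    from two kinds of survey responses: paired comparisons (which of two
    health states is healthier) and population health equivalence choices
    (trading a program that averts 1000 rapid deaths against one averting M
    nonfatal lifelong cases). Paired comparisons are scaled with a
    Thurstonian probit model fitted by maximum likelihood; equivalence
    choices are converted to interval-censored observations and fitted by
    interval regression; a linear anchoring regression maps the latent
    probit index onto the 0-1 DW scale; means and 95% uncertainty intervals
    come from Monte Carlo integration and a respondent-level bootstrap.
    Includes a survey simulator (pair randomisation by minimum selection
    counts, repeated-pair placement, quality-control filters) so the whole
    pipeline is testable end to end, plus distributional and cross-survey
    comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    jsonlite,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
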