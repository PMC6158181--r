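Package: egonets
Title: Egocentric Social Network Metrics and Outcome Association from
    Structured Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns wide-format personal-network survey exports (one row per
    respondent, pairwise tie-strength items for the first ten named contacts,
    per-contact attribute and health-habit items) into quantitative egocentric
    network metrics: structural measures (size, density, Burt constraint,
    effective size, maximum and mean degree) and compositional measures
    (percent kin, age spread, sex and race diversity by the index of
    qualitative variation, health-habit percentages).  Associates these
    metrics with a clinical outcome through covariate-adjusted linear
    regression with Benjamini-Hochberg false-discovery control within metric
    categories, and through a category-level omnibus test that combines
    per-variable p-values by Fisher's method against a permutation null that
    shuffles the outcome.  Includes sociogram montages and quantile-quantile
    plots with permutation confidence envelopes, a synthetic-cohort generator
    for end-to-end testing without participant data, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    igraph,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
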