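Package: healthrankr
Title: Composite Health Scoring and Within-State Ranking of Counties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scoring engine for county-level population health surveillance
    in the style of the annual County Health Rankings. From a county-by-measure
    table it computes within-state standardized Z-scores with mean imputation,
    reliability flagging and small-county truncation, aggregates them into
    weighted health-outcome and health-factor composite scores, ranks counties
    within each state with competition ranking, assigns quartiles, flags
    counties with insufficient mortality data as unrankable, and computes
    direction-aware national best-10% benchmarks and healthiest versus
    least-healthy extremes comparisons. Ships the 2014 measure catalog as the
    default weighted hierarchy and a synthetic multi-state county generator
    with a latent health factor so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
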