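Package: vstmbind
Title: Object-Location Binding Analysis for Delayed-Reproduction Visual
    Short-Term Memory Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the 'What was where?' delayed-reproduction paradigm
    used to study object-location binding in visual short-term memory.
    Generates constrained session designs (stimulus placement in degrees of
    visual angle, balanced load/delay blocks, identity-repeat limits),
    simulates participant reports from a target/swap/guess mixture model
    with group presets for familial Alzheimer's disease cohorts, scores the
    four behavioural outcomes (two-alternative identification, gross
    localization error, nearest-neighbour precision, swap errors with
    Monte-Carlo chance correction), and provides covariate-adjusted group
    comparisons, factorial interaction tests, bias-corrected accelerated
    (BCa) bootstrap confidence intervals, and hippocampal-volume
    association models on subject summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
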