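Package: quintree
Title: Qualitative Interaction Trees for Two-Arm Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions participants of a two-arm randomized trial into
    treatment-responder, iatrogenic-responder and nonresponder subgroups with
    qualitative interaction trees (QUINT): greedy recursive partitioning on a
    criterion balancing within-leaf treatment effect size against leaf
    cardinality, exhaustive leaf-class assignment, and tree-size selection by
    bias-corrected bootstrap optimism. Includes derivation of heavy-drinking-day
    outcomes from timeline-followback daily drinking records, chained-regression
    imputation of baseline predictors, two missing-outcome strategies, bootstrap
    optimism validation of the effect-size range, cross-outcome model
    comparison, and a synthetic trial generator with planted subgroups for
    method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
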