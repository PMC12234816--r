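Package: moodtrees
Title: Simulation of DSM-IV-TR Mood Disorder Diagnoses and Their Decision-Tree Approximations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cohorts of correlated binary psychiatric symptoms with a
    Gaussian copula calibrated to target marginal prevalence and pairwise phi
    correlation, derives DSM-IV-TR diagnoses of major depressive episodes,
    dysthymic disorder and manic episodes from declarative count-threshold
    rules, approximates each diagnosis with cross-validation-pruned
    classification trees, and aggregates sensitivity, specificity and
    symptom-usage statistics over a prevalence-by-correlation grid.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rpart,
    stats,
    utils,
    tools,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
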