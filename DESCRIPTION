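Package: rxanomaly
Title: Distance-Based Anomaly Detection for Radiotherapy Prescriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flags suspicious radiotherapy prescriptions by comparing a new
    treatment course against a per-technique historical cohort. A prescription
    distance (Euclidean, over min-max scaled fractions and dose per fraction)
    and a feature distance (equal-weight Gower over mixed clinical features)
    are averaged over the closest historical neighbours to give two scores,
    R and F, which are compared with thresholds patterned on cohort-level
    characteristic distances. Includes the two-threshold decision tree with
    type I (rare prescription) and type II (prescription-feature mismatch)
    verdicts, threshold tuning by adaptive parameter search against an f1
    objective, simulated-anomaly synthesis with conditional-distribution
    rarity verification, and a synthetic cohort generator for end-to-end
    evaluation without access to restricted clinical data.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
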