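Package: pltmarkers
Title: Lexico-Semantic Markers from Property-Listing Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts word-property markers of semantic memory navigation from
    coded property-listing-task transcripts: psycholinguistic norm profiles
    (concreteness, imageability, familiarity, frequency, phoneme length),
    embedding-based semantic variability and property distance flow, taxonomy
    granularity, and production-frequency relevance/distinctiveness. Provides
    group-level inference (IQR outlier fencing, one-way ANCOVA with an
    education covariate, Tukey-Kramer post hocs with Cohen's d), subject-level
    classification via repeated stratified cross-validated gradient boosting,
    distribution-gated clinical correlations, and a synthetic-cohort generator
    with parameterized group effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
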