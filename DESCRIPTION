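Package: verbgen
Title: Scoring and Cohort Analysis of Auditory Verb Generation Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing auditory noun-to-verb generation tasks in
    clinical cohorts, in particular primary progressive aphasia (PPA).
    Provides response coding against a reference lexicon with a four-way
    error taxonomy (related verb, not-a-verb, unrelated verb, missing),
    control-derived per-noun agreement indices (response entropy, the
    association strength index and the competition strength index),
    per-subject accuracy and error-consistency profiles with standard
    two-standard-deviation outlier exclusion, lexico-semantic response
    features (light-verb usage, unique-verb dispersion, and a decomposition
    of not-a-verb errors into stimulus repetitions and semantically related
    nouns via word-embedding cosine similarity), group-level statistics
    (one-way and mixed group-by-error-type ANOVAs with Tukey post hoc tests,
    Bonferroni-corrected by-item and by-subject correlations), and
    diagnostic-group classification with a depth-limited decision tree
    evaluated by stratified cross-validation against a label-permutation
    estimate of chance. A synthetic-data generator reproduces the
    statistical structure of a typical study (control agreement spans,
    variant-specific error mixtures, psycholinguistic norms, toy embedding
    tables) so the full pipeline can be exercised without patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
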