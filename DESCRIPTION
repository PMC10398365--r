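Package: cessalex
Title: Emotion-Lexicon Profiling of Substance-Cessation Support-Forum Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lexicon-based pipeline for profiling emotional expression in
    text posts from online support forums, built around the comparison of
    substance-cessation communities with general-interest control forums.
    Provides curated emotion and time word banks, text normalisation,
    corpus inclusion filters, normalised emotion occurrence-frequency
    profiles, percentile-based outlier detection against a control sample,
    pairwise cosine-similarity profiling with top-k emotional neighbours,
    and abstinence-duration analyses (first-day posting burst, log-spaced
    time-binned emotion trajectories, two-way ANOVA and Bonferroni-corrected
    post-hoc contrasts). A synthetic forum-corpus generator with ground-truth
    records supports parameter-recovery and calibration studies.
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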