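Package: screensim
Title: Retrospective Simulation of Prioritized Title/Abstract Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate active-learning (prioritized) title/abstract
    screening for systematic reviews by replaying recorded screening labels
    through an iterative rank-and-screen simulation. Records are screened in
    fixed-size iterations (2% of the dataset, clamped to 25-200 records); a
    relevance model is refit after each iteration and the remaining records
    are re-ranked by predicted likelihood of inclusion. The package locates
    the iteration at which a true-recall target (default 95%) is reached and
    computes reviewer-relevant outcomes: screening burden, title/abstract
    false negatives, missed final includes, and hours saved under a modified
    screening approach. Includes labeled-corpus input/output (CSV and RIS), a
    synthetic corpus generator with tunable text-label signal, pluggable
    relevance scorers (TF-IDF logistic, oracle, random), replicate
    aggregation (mean/SD, median/range/IQR), and a full experiment driver.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    glmnet,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
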