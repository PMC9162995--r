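Package: trialfragility
Title: Fragility Metrics for Two-Arm Trials with Dichotomous Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-comparison fragility metrics for two-arm trials
    with dichotomous outcomes summarised as 2x2 tables: the two-sided
    conditional exact (Fisher) P value, its Shannon S-value transform, the
    fragility index and reverse fragility index with their quotients,
    relative risk, and the exact power of Fisher's test by full binomial
    enumeration. Provides corpus-level summaries (medians with
    interquartile ranges, bootstrap Spearman correlations, Mood's median
    test, histogram tables, allocation-ratio sensitivity subsets), a
    validated CSV interchange format for trial-comparison corpora, and a
    reproducible synthetic corpus generator built on a two-proportion
    sample-size calculation, so the whole pipeline can be exercised
    without access to any particular extraction dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
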