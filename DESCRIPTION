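Package: gmosr
Title: Scoring and Normative Percentile Ranks for the General Movement
    Optimality Score-Revised (GMOS-R)
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the General Movement Optimality Score-Revised
    (GMOS-R), a detailed 0-38 assessment of infant general movements.
    Provides a validating scoring engine for the revised scoresheet
    (per-region subscores, half-point items, ceiling rounding of the
    total), classification of recordings into postmenstrual-age periods
    and of countries into World Bank income groups, encoded normative
    percentile-rank tables with band lookup stratified by income group
    and recording age, unsmoothed empirical percentile computation on
    tied ordinal scores, tie-corrected Mann-Whitney and Kruskal-Wallis
    tests with interrater agreement statistics (pairwise ICC, Cohen's
    kappa, within-delta agreement), and a seeded synthetic cohort
    simulator so that every component can be exercised without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
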