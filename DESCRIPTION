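Package: apneafs
Title: Wrapper Feature Selection and Classification for Sleep Apnea Tabular Data
Version: 0.1.0
Authors@R: person("Sleep Informatics", "Maintainers",
    email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for diagnosing obstructive sleep apnea from
    demographic and polysomnographic summary features: mixed-type table
    preprocessing (sparse-column removal, mean/mode imputation, min-max
    normalization, Epworth sleepiness banding), demographic grouping by race,
    sex and age, binary particle swarm optimization (BPSO) wrapper feature
    selection with S-shaped transfer functions, k-nearest-neighbour and
    random-subspace discriminant classifiers, stratified K-fold evaluation with
    an imbalance-aware metric suite (balanced accuracy, G-mean, F-score),
    Friedman mean-rank and Wilcoxon signed-rank model comparison, and a seeded
    synthetic-data generator with planted informative features for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
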