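Package: artmeta
Title: Phylogenetic Multilevel Meta-Analysis of Post-Mating Investment in
    Alternative Reproductive Tactics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing sperm and ejaculate investment between male
    alternative reproductive tactics (e.g. sneakers versus guarders) by
    meta-analysis. Computes Hedges' d and its sampling variance from group
    summaries, t and Mann-Whitney U statistics, and partial eta-squared from
    ANCOVA re-analyses of raw testes allometry data; builds phylogenetic
    correlation matrices from Newick trees (unit branch lengths, Grafen
    ultrametricisation); fits multilevel random-effects meta-analytic models
    by restricted maximum likelihood with phylogeny, species, study and
    observation random factors and optional within-experiment effect-size
    correlation; partitions heterogeneity (I-squared) across levels; runs
    moderator meta-regressions with omnibus Q_M tests and marginal R-squared;
    provides publication-bias diagnostics (precision and publication-year
    meta-regressions); contrasts gonadosomatic-index and ANCOVA estimates of
    relative testes investment; and generates synthetic datasets with the
    full assumed covariance structure for testing and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
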