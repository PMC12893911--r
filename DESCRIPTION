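Package: microrank
Title: Microbiome Species Health and Diet Rankings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds health and diet rankings of gut microbial species
    (species-level genome bins, SGBs) from covariate-adjusted partial
    Spearman correlations between relative abundances and panels of host
    health and diet markers, aggregated into percentile ranks across marker
    categories and cohorts. Scores individual metagenomic samples against a
    ranking (extreme-set counts, cumulative abundances, normalized rank-sum
    scores), pools per-cohort adjusted effects with Paule-Mandel
    random-effects meta-analysis including shared-control covariance,
    analyses paired pre/post dietary-intervention designs (Wilcoxon
    signed-rank with Benjamini-Hochberg correction and rank-shift
    enrichment), and provides a repeated-holdout association harness with
    group-aware stratified splits. Includes a zero-inflated log-normal
    compositional simulator of multi-cohort abundance, marker and metadata
    collections with planted favourable and unfavourable species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    randomForest,
    metafor,
    optparse
Config/testthat/edition: 3
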