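---
title: "Ranking gut species by host health and diet markers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking gut species by host health and diet markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(microrank)
```

## The problem

Large cross-sectional microbiome cohorts pair shotgun-metagenomic
taxonomic profiles — relative abundances of species-level genome bins
(SGBs) — with panels of host markers: anthropometric and clinical
("personal"), fasting blood markers, postprandial responses, and
diet-quality indices. `microrank` turns such collections into a single
per-species ranking of association with host health, and provides the
downstream machinery that makes such a ranking useful: scoring individual
samples, validating against case-control collections by meta-analysis,
and testing whether dietary interventions move favourably ranked species.

The package operates on three objects: an `abundance_table` (samples x
SGBs, fractions in [0, 1] with an unclassified remainder allowed), a
marker matrix (samples x markers), and a `marker_panel` assigning each
marker a category and a health direction (+1 if a higher value is
healthier).

## The ranking procedure

For each cohort separately:

1. **Prevalence filter.** Only SGBs present (abundance > 0) in strictly
   more than 20% of samples are ranked. The strict inequality is
   deliberate: an SGB present in exactly 20% of samples is dropped.
2. **Partial Spearman correlation.** For each (SGB, marker) pair, all
   variables — abundances *including zeros*, the marker, and the
   covariates sex, age and BMI — are average-tie rank-transformed; the
   SGB and marker ranks are each residualized on the covariate ranks
   plus an intercept by least squares, and the Pearson correlation
   ρ of the residuals is taken. With no covariates this is exactly
   Spearman's ρ. P-values use the t distribution on n − 2 − k degrees
   of freedom but play no role in ranking: the method is driven by the
   ordering of correlations, not their significance.
3. **Percentiles.** Each correlation is oriented by the marker's
   direction (`oriented = direction × ρ`) and SGBs are sorted by
   descending oriented score; the percentile is the average-tie
   fractional rank divided by the number of ranked SGBs, so values lie
   in (0, 1] and the SGB most favourably correlated with health gets
   the smallest percentile.
4. **Aggregation.** Percentiles are averaged over markers within each
   category, the personal/fasting/postprandial category means are
   averaged into the cohort health value (the dietary category mean is
   kept separate as the cohort diet value), and finally cohort values
   are averaged across cohorts. An SGB must be ranked in at least two
   cohorts to receive a final health-rank or diet-rank.

Two conventions deserve an explicit statement because the verbal
description "sorted ascending if the marker was positive" is ambiguous:

* **Orientation.** We orient so that percentile → 0 means "positively
  correlated with healthier marker values". This is the reading under
  which favourably ranked species behave favourably in every downstream
  analysis, and it is the one consistent with heat-map descriptions of
  this family of rankings.
* **Score normalization.** When scoring samples, each final rank r is
  mapped to s = 1 − 2r ∈ [−1, 1], so favourable species contribute
  positively and a healthier microbiome gets a *higher* rank-sum score.
  The convention is recorded in the score report's `"normalization"`
  attribute; flipping it flips the sign of every downstream effect
  size, nothing else.

A correlation cell is treated as "not ranked in this cohort" when fewer
than 30 complete cases survive pairwise deletion (`min_n = 30`). No
published threshold exists for this; 30 bounds the rank noise of a
single correlation and is exposed as a parameter. Cohorts missing a
whole category (for instance a cohort that collected no food-frequency
questionnaire) simply contribute no value for that category: averages
are taken over what is present.

Cross-cohort agreement is summarized two ways: Spearman concordance of
two rank vectors on their shared SGBs, and the intraclass correlation
coefficient. We use the single-measurement, absolute-agreement ICC
under the two-way random-effects model — ICC(2,1) in the
Shrout–Fleiss taxonomy — computed from the two-way ANOVA mean squares
with SGBs as targets and cohorts as raters. The ICC variant is a
genuine design choice (the agreement literature offers six); absolute
agreement is the right one here because a cohort that systematically
shifts all percentiles *should* be penalized.

## Sample scoring

`score_samples()` summarizes a sample against a ranking by: the number
of members of the k most favourable and k most unfavourable species
present (k = 50 by default, ties at the set boundary broken by SGB id);
their cumulative relative abundances, arcsine-square-root transformed
*after* summation; the rank-sum score Σs over ranked species present;
and an abundance-weighted variant Σ s·asin(√a) that damps the
compositional dominance of highly abundant species. "Present" means
abundance strictly greater than zero, matching the richness definition;
no detection threshold is applied.

## Effect estimation and meta-analysis

Per-cohort group contrasts (BMI categories, case vs control) are
estimated by OLS of the outcome on an intercept, a 0/1 group indicator
(reference = control or lower-BMI group) and covariates; the adjusted
coefficient is standardized into an SMD by dividing by the pooled
within-group SD of the outcome (`beta_to_smd()`). This is the standard
conversion; it is isolated in one function so an alternative
denominator is a one-line swap.

Pooling uses the Paule–Mandel random-effects estimator: τ² solves
Σ wᵢ(τ²)(yᵢ − ȳ(τ²))² = k − 1 with wᵢ = 1/(vᵢ + τ²). The left side is
monotone decreasing in τ², so we bisect on [0, 100·max vᵢ] (expanding
the bracket if needed) to an interval width of 1e-8, clamping to zero
when the criterion is already below k − 1 at τ² = 0. Confidence
intervals are normal-theory ±1.96·se throughout; no small-sample
(Knapp–Hartung) adjustment is applied.

When two studies reuse one control arm their SMDs are correlated; the
covariance uses the standard multi-arm approximation
cov = 1/n_c + smdᵢ·smdⱼ/(2(nᵢ + nⱼ)), and pooling is by generalized
least squares with the inverse of the full covariance matrix, which
reduces exactly to inverse-variance weighting when the matrix is
diagonal. The approximation assumes the shared arm is (essentially) the
whole control arm of both studies; with very asymmetric sharing the
approximate matrix can lose positive definiteness, in which case the
function errors after one tiny-jitter attempt rather than silently
proceeding.

Binomial sign tests on counts of concordant comparisons are exact, with
the two-sided p obtained by doubling the smaller tail (capped at 1).
Published analyses of this kind are not always explicit about
sidedness — some printed values are reproducible only as one-sided
tails — so `alternative` is exposed, defaulting to two-sided.
Country contrasts spanning several datasets use a linear mixed model
with a random intercept per dataset and fixed effects for country and
sequencing depth, falling back to depth-adjusted OLS (with a message)
when each country has a single dataset.

## Intervention analysis

`prepost_differential()` gates SGBs at ≥10% prevalence at *both*
timepoints, then applies the two-sided Wilcoxon signed-rank test to the
paired abundances. Zero within-pair differences are dropped (the
standard signed-rank convention; the alternative of keeping them is a
different test, not a parameter), the exact null distribution is used
up to 25 informative untied pairs, and the normal approximation with
tie correction beyond that. The effect size is log₂(mean endpoint /
mean baseline) on raw fractions without a pseudocount — the prevalence
gate makes zero means practically impossible — with a 1e-8 guard for
degenerate inputs. Q values are Benjamini–Hochberg. Significance
thresholds are configuration, not constants: Q < 0.01 and Q < 0.1 are
both in common use depending on cohort size and design.
`rank_shift_enrichment()` then asks whether the significantly
increasing SGBs carry more favourable ranks than the decreasing ones
(two-sided Mann–Whitney U), requiring at least 3 ranked SGBs per side
and reporting how many significant SGBs lacked a rank.

## The repeated-holdout harness

The association-strength harness deliberately does *not* own a
learner: the model is injected as a factory `function(X, y, task)`
returning a scoring function. The documented default is a 1000-tree
random forest with √p features per split (`rf_factory()`); a
ridge-stabilised linear factory (`lm_factory()`) is provided for
calibration work where the learner is not under study. Continuous
targets become classification problems through quartile contrasts
(1v4 excluding the middle half, 123v4, 1v234), with quartiles assigned
by average-tie fractional rank so boundary ties are deterministic.
Splits are 80:20, repeated (100 by default), stratified by class at the
group level, and groups — twin pairs — are never divided across folds.
Stratum iteration order is canonicalized by group content rather than
label value so that relabelling cannot change the drawn folds. A
repeat whose training fold lacks a class is redrawn, at most 10 times.
Metrics are AUC (rank-based) for classification and Spearman between
truth and prediction for regression.

## The synthetic-data generator

The generator exists so every stage can be tested with planted ground
truth and no data download. Its model:

* **Abundances** are zero-inflated log-normal: per-SGB presence
  probabilities drawn uniformly from [0.3, 0.95] (case-control:
  [0.25, 0.9]; intervention: [0.15, 0.9]), log-abundance means drawn
  N(0, 1) once per universe, within-SGB log SD 1. Each sample's raw
  abundances are closed to a random total in [0.85, 1], mimicking the
  unclassified fraction of real profiles. All cohorts share the
  universe parameters, so the same species is common or rare
  everywhere, with cohort-specific samples.
* **Markers** are built from the *rank-transformed* planted-SGB
  abundances: a latent health signal Σ dᵢ·e·z(rank(xᵢ))/√m plus
  loadings on standardized sex, age and BMI (defaults 0.2, −0.15,
  −0.3 on the healthy scale), multiplied by the marker's direction and
  perturbed with unit-SD noise. Because the signal is linear in
  abundance ranks, the planted effect is exactly the quantity the
  partial Spearman stage estimates — by design, so that parameter
  recovery is a sharp test of the ranking machinery rather than of a
  distributional approximation.
* **Confounding switch.** With `bmi_confounding > 0`, half of the null
  SGBs load positively and half negatively on standardized BMI. Since
  all markers also load on BMI, an unadjusted analysis ranks these
  null species spuriously; the covariate-adjusted ranking should not.
* **Case-control collections** shift the planted SGBs in cases against
  their health direction, in both log-abundance mean and presence
  log-odds, by `case_shift`; because the shift acts on the log scale
  the induced depletion is proportional to abundance. `case_shift = 0`
  gives an exchangeable null. Optionally two datasets share one
  control arm to exercise shared-control pooling.
* **Paired designs** re-draw each subject's endpoint log-abundance
  around the baseline value (within-subject SD 0.5) and add a planted
  log₂ shift to a response set; presence patterns persist within
  subject, so a zero shift is an exchangeable pre/post null.

What the generator does *not* emulate — and therefore what passing
tests do not establish about real data — includes: real taxonomic
structure and phylogenetic correlation between species, over-dispersed
sequencing noise, batch effects beyond a scalar dataset offset,
marker-marker correlation structure beyond the shared latent signal,
and non-linear or interaction effects of covariates. Parameter-recovery
results show the estimator chain is correct under its own assumptions,
not that those assumptions hold in any particular cohort.

## Problem sizes and reproducibility

The standard parameter-recovery scenario is 3 cohorts × 500 samples ×
200 SGBs with 20 favourable and 20 unfavourable planted species at
effect 0.4 — large enough that recovery is stable across seeds, small
enough to run in seconds. Calibration suites use 200 null case-control
collections (5 datasets × 40/arm × 60 SGBs) and 50 null paired
collections (40 subjects × 100 SGBs). All generators are pure
functions of their seed; the staged pipeline (`run_pipeline()`) fans a
single master seed into named per-stage substreams, so identical
configuration and seed give byte-identical TSV outputs, and adding or
removing a stage does not perturb the others.

```{r example}
truth <- planted_truth(sgb_universe(80), 8, 8, effect_size = 0.5)
cfgs <- lapply(1:2, function(i)
  cohort_sim_config(paste0("C", i), 150, 80, seed = 10 + i))
sim <- generate_multi_cohort(cfgs, truth)
meta <- do.call(rbind, lapply(sim$cohorts, `[[`, "meta"))
rk <- rank_species(lapply(sim$cohorts, `[[`, "table"),
                   lapply(sim$cohorts, `[[`, "markers"),
                   meta, sim$panel)
head(rk[order(rk$health_rank), c("sgb_id", "health_rank", "diet_rank")])
```

## Known limitations

* The ranking is associational; no causal claim survives the pipeline,
  and the package deliberately offers no machinery suggesting one.
* The ≥2-cohort retention rule and the `min_n = 30` cell rule are
  coarse guards against rank noise, not optimized thresholds.
* Whether prevalence should be computed per cohort before ranking or on
  pooled data is not settled; the per-cohort default is a parameter
  (`prevalence` in `rank_species()`), flagged for sensitivity analysis.
* The shared-control covariance is an approximation that can fail
  positive definiteness under asymmetric arm sharing (see above).
* The rank-sum score is a one-dimensional summary: it usefully orders
  microbiomes along the favourable/unfavourable axis but is not a
  condition-specific classifier and should not be evaluated as one.
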