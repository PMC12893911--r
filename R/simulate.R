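#' Default synthetic marker panel
#'
#' A compact stand-in for a cardiometabolic marker panel: three personal,
#' four fasting and three postprandial markers feeding the health ranking,
#' and five diet-quality indices feeding the diet ranking. Directions
#' follow the usual clinical reading (e.g. HDL and diet-quality indices
#' higher-is-healthier; triglycerides, inflammation and postprandial
#' excursions higher-is-worse).
#'
#' @return a [marker_panel] with 15 markers.
#' @export
default_marker_panel <- function() {
  marker_panel(
    marker = c("ascvd_risk", "blood_pressure", "visceral_fat",
               "hdl", "triglycerides", "glyca", "fasting_glucose",
               "pp_glucose_iauc", "pp_triglycerides", "pp_insulin",
               "hei", "hpdi", "amed", "hfd", "updi"),
    category = c(rep("personal", 3), rep("fasting", 4),
                 rep("postprandial", 3), rep("dietary", 5)),
    direction = c(-1, -1, -1,
                  1, -1, -1, -1,
                  -1, -1, -1,
                  1, 1, 1, 1, -1))
}

#' Planted ground truth
#'
#' Designates which SGBs of the simulated universe are favourable
#' (`effect_direction = +1`: higher abundance goes with healthier marker
#' values), unfavourable (`-1`) or null (`0`), and the standardized marker
#' shift per unit of rank-transformed abundance.
#'
#' @param sgb_ids the full SGB universe.
#' @param n_favourable,n_unfavourable counts of planted species; the first
#'   `n_favourable` ids are favourable and the next `n_unfavourable`
#'   unfavourable (disjoint by construction).
#' @param effect_size standardized effect per planted SGB.
#' @return a `planted_truth` data.frame: `sgb_id`, `effect_direction`,
#'   `effect_size`.
#' @export
planted_truth <- function(sgb_ids, n_favourable, n_unfavourable,
                          effect_size = 0.4) {
  stopifnot(n_favourable >= 0, n_unfavourable >= 0,
            n_favourable + n_unfavourable <= length(sgb_ids))
  dir <- integer(length(sgb_ids))
  dir[seq_len(n_favourable)] <- 1L
  dir[n_favourable + seq_len(n_unfavourable)] <- -1L
  structure(data.frame(sgb_id = sgb_ids, effect_direction = dir,
                       effect_size = ifelse(dir == 0, 0, effect_size),
                       stringsAsFactors = FALSE),
            class = c("planted_truth", "data.frame"))
}

#' Simulation configuration for one cohort
#'
#' @param cohort_id cohort label.
#' @param n_samples,n_sgbs cohort size and SGB universe size.
#' @param zero_inflation range of per-SGB presence probabilities (uniform).
#' @param log_abundance_sd SD of per-SGB log abundance when present.
#' @param panel the [marker_panel] to emit markers for.
#' @param marker_noise_sd SD of marker noise (signal is on unit scale).
#' @param covariate_effects named loadings of standardized sex/age/BMI on
#'   the healthy-direction marker scale.
#' @param cohort_shift additive mean offset applied to every marker.
#' @param bmi_confounding strength of a BMI load planted on half of the
#'   null SGBs (positive on one half, negative on the other), used to
#'   demonstrate that covariate adjustment removes spurious rankings.
#' @param seed mandatory RNG seed.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(cohort_id, n_samples, n_sgbs,
                              zero_inflation = c(0.3, 0.95),
                              log_abundance_sd = 1,
                              panel = default_marker_panel(),
                              marker_noise_sd = 1,
                              covariate_effects = c(sex = 0.2, age = 0.15,
                                                    bmi = 0.3),
                              cohort_shift = 0,
                              bmi_confounding = 0,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_samples > 0, n_sgbs > 0, length(zero_inflation) == 2,
            zero_inflation[1] > 0, zero_inflation[2] <= 1)
  structure(list(cohort_id = cohort_id, n_samples = as.integer(n_samples),
                 n_sgbs = as.integer(n_sgbs),
                 zero_inflation = zero_inflation,
                 log_abundance_sd = log_abundance_sd, panel = panel,
                 marker_noise_sd = marker_noise_sd,
                 covariate_effects = covariate_effects,
                 cohort_shift = cohort_shift,
                 bmi_confounding = bmi_confounding,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Synthetic SGB universe ids
#' @param n_sgbs universe size.
#' @return character vector `simSGB0001 ... simSGB<n>`.
#' @export
sgb_universe <- function(n_sgbs) sprintf("simSGB%04d", seq_len(n_sgbs))

# zero-inflated log-normal abundances closed to a random total in
# [0.85, 1], mimicking the unclassified remainder. Returns the closed
# fractions together with the raw log-abundance components.
.sim_abundance <- function(n, presence_p, meanlog, sdlog, sample_ids,
                           sgbs, total_range = c(0.85, 1)) {
  p <- length(presence_p)
  pres <- matrix(stats::runif(n * p), n, p) < rep(presence_p, each = n)
  logab <- matrix(stats::rnorm(n * p, mean = rep(meanlog, each = n),
                               sd = sdlog), n, p)
  raw <- ifelse(pres, exp(logab), 0)
  totals <- stats::runif(n, total_range[1], total_range[2])
  rs <- rowSums(raw)
  scale <- ifelse(rs > 0, totals / rs, 0)
  vals <- raw * scale
  dimnames(vals) <- list(sample_ids, sgbs)
  list(values = vals, pres = pres, logab = logab)
}

.z <- function(v) {
  s <- stats::sd(v)
  if (is.na(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

# markers as direction-consistent linear combinations of rank-transformed
# planted-SGB abundances plus covariate effects and noise
.sim_markers <- function(values, truth, panel, covars, config) {
  n <- nrow(values)
  planted <- truth$sgb_id[truth$effect_direction != 0]
  signal <- rep(0, n)
  if (length(planted) > 0) {
    zr <- apply(values[, planted, drop = FALSE], 2,
                function(v) .z(rank(v, ties.method = "average")))
    w <- truth$effect_direction[match(planted, truth$sgb_id)] *
      truth$effect_size[match(planted, truth$sgb_id)]
    signal <- as.numeric(zr %*% w) / sqrt(length(planted))
  }
  ce <- config$covariate_effects
  healthy <- signal +
    ce[["sex"]] * .z(covars$sex) -
    ce[["age"]] * .z(covars$age) -
    ce[["bmi"]] * .z(covars$bmi)
  mk <- sapply(seq_len(nrow(panel)), function(j) {
    panel$direction[j] * healthy + config$cohort_shift +
      stats::rnorm(n, sd = config$marker_noise_sd)
  })
  dimnames(mk) <- list(rownames(values), panel$marker)
  mk
}

.sim_covariates <- function(n) {
  list(sex = stats::rbinom(n, 1, 0.5),
       age = stats::runif(n, 18, 75),
       bmi = pmax(18.6, stats::rnorm(n, 26, 4)))
}

#' Generate a multi-cohort collection with planted truth
#'
#' Emulates a set of cross-sectional cohorts sharing one SGB universe and
#' one planted truth: abundances are zero-inflated log-normal closed to a
#' random per-sample total, markers are direction-consistent linear
#' combinations of the rank-transformed planted-SGB abundances plus
#' covariate effects and noise, so the planted signal is exactly the
#' quantity partial Spearman correlation estimates. Reproducible given the
#' per-cohort seeds.
#'
#' @param configs list of [cohort_sim_config]s sharing `n_sgbs`.
#' @param truth a [planted_truth] over the shared universe.
#' @return list with named per-cohort elements (`table`, `markers`,
#'   `meta`) under `$cohorts`, plus `$truth` and `$panel`.
#' @export
generate_multi_cohort <- function(configs, truth) {
  if (length(configs) < 1) stop("at least one cohort config is required")
  n_sgbs <- unique(vapply(configs, `[[`, integer(1), "n_sgbs"))
  if (length(n_sgbs) != 1)
    stop("inconsistent SGB universes across cohort configs")
  sgbs <- sgb_universe(n_sgbs)
  if (!all(truth$sgb_id %in% sgbs))
    stop("planted truth refers to SGBs outside the shared universe")
  # universe-level parameters shared by all cohorts, derived from the
  # first cohort's seed so the collection is a pure function of configs
  set.seed(configs[[1]]$seed + 990001L)
  presence_p <- stats::runif(n_sgbs, configs[[1]]$zero_inflation[1],
                             configs[[1]]$zero_inflation[2])
  meanlog <- stats::rnorm(n_sgbs, 0, 1)
  null_ids <- setdiff(sgbs, truth$sgb_id[truth$effect_direction != 0])
  conf_pos <- null_ids[seq_len(floor(length(null_ids) / 2))]
  conf_neg <- setdiff(null_ids, conf_pos)
  cohorts <- lapply(configs, function(cfg) {
    set.seed(cfg$seed)
    n <- cfg$n_samples
    ids <- sprintf("%s_S%05d", cfg$cohort_id, seq_len(n))
    cov <- .sim_covariates(n)
    sim <- .sim_abundance(n, presence_p, meanlog, cfg$log_abundance_sd,
                          ids, sgbs)
    if (cfg$bmi_confounding != 0) {
      zb <- .z(cov$bmi)
      adj <- sim$logab
      adj[, match(conf_pos, sgbs)] <- adj[, match(conf_pos, sgbs)] +
        cfg$bmi_confounding * zb
      adj[, match(conf_neg, sgbs)] <- adj[, match(conf_neg, sgbs)] -
        cfg$bmi_confounding * zb
      raw <- ifelse(sim$pres, exp(adj), 0)
      totals <- rowSums(sim$values)
      rs <- rowSums(raw)
      sim$values <- raw * ifelse(rs > 0, totals / rs, 0)
      dimnames(sim$values) <- list(ids, sgbs)
    }
    tab <- abundance_table(sim$values)
    mk <- .sim_markers(sim$values, truth, cfg$panel, cov, cfg)
    meta <- data.frame(sample_id = ids, cohort_id = cfg$cohort_id,
                       subject_id = ids, sex = cov$sex, age = cov$age,
                       bmi = cov$bmi, stringsAsFactors = FALSE)
    list(table = tab, markers = mk, meta = meta)
  })
  names(cohorts) <- vapply(configs, `[[`, character(1), "cohort_id")
  list(cohorts = cohorts, truth = truth, panel = configs[[1]]$panel)
}

#' Generate a case-control collection
#'
#' Emulates a set of public case-control datasets over one SGB universe:
#' within each dataset, case samples have the planted SGBs shifted in
#' log abundance and presence probability by `case_shift` against the
#' health direction — cases are depleted in favourable SGBs and enriched
#' in unfavourable ones. Optionally the first two datasets share one
#' control arm (identical samples under identical ids) to exercise
#' shared-control pooling; the overlap map is attached as attribute
#' `"overlap"`.
#'
#' @param n_datasets number of datasets.
#' @param n_per_arm samples per arm (scalar or length `n_datasets`).
#' @param truth a [planted_truth].
#' @param case_shift log-fold shift applied against health direction in
#'   cases (0 gives an exchangeable null).
#' @param seed RNG seed.
#' @param shared_controls reuse dataset 1's control arm in dataset 2.
#' @return list of datasets, each `(table, meta)`, with attribute
#'   `"overlap"` (named list of shared control ids, possibly empty).
#' @export
generate_case_control_collection <- function(n_datasets, n_per_arm, truth,
                                             case_shift = 0, seed,
                                             shared_controls = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  n_per_arm <- rep_len(n_per_arm, n_datasets)
  if (any(n_per_arm < 4)) stop("at least 4 samples per arm are required")
  if (shared_controls && n_datasets < 2)
    stop("shared controls need at least two datasets")
  sgbs <- truth$sgb_id
  p <- length(sgbs)
  dir <- truth$effect_direction
  set.seed(seed + 770001L)
  presence_p <- stats::runif(p, 0.25, 0.9)
  meanlog <- stats::rnorm(p, 0, 1)
  qlogis_p <- stats::qlogis(presence_p)
  datasets <- vector("list", n_datasets)
  overlap <- list()
  for (d in seq_len(n_datasets)) {
    set.seed(seed + d)
    n <- n_per_arm[d]
    ds_shift <- stats::rnorm(1, 0, 0.2)     # dataset-level batch offset
    make_arm <- function(arm, ids) {
      shift <- if (arm == "case") -dir * case_shift else 0
      pp <- stats::plogis(qlogis_p + shift)
      ml <- meanlog + ds_shift + shift
      sim <- .sim_abundance(n, pp, ml, 1, ids, sgbs)
      cov <- .sim_covariates(n)
      meta <- data.frame(sample_id = ids,
                         cohort_id = sprintf("ds%02d", d),
                         sex = cov$sex, age = cov$age, bmi = cov$bmi,
                         status = arm, stringsAsFactors = FALSE)
      list(table = abundance_table(sim$values), meta = meta)
    }
    if (shared_controls && d == 2) {
      ctl <- datasets[[1]]$control_arm
      overlap[["ds01:ds02"]] <- ctl$meta$sample_id
    } else {
      ctl <- make_arm("control", sprintf("ds%02d_C%04d", d, seq_len(n)))
    }
    cse <- make_arm("case", sprintf("ds%02d_D%04d", d, seq_len(n)))
    ctl_meta <- ctl$meta
    ctl_meta$cohort_id <- sprintf("ds%02d", d)
    tab <- abundance_table(rbind(unclass(ctl$table), unclass(cse$table)))
    datasets[[d]] <- list(table = tab,
                          meta = rbind(ctl_meta, cse$meta),
                          control_arm = ctl)
    rownames(datasets[[d]]$meta) <- NULL
  }
  names(datasets) <- sprintf("ds%02d", seq_len(n_datasets))
  datasets <- lapply(datasets, function(d) d[c("table", "meta")])
  attr(datasets, "overlap") <- overlap
  datasets
}

#' Generate a paired pre/post intervention collection
#'
#' Emulates a within-arm dietary-intervention design: every subject has a
#' baseline and an endpoint sample; the endpoint log abundance is a
#' re-draw around the subject's baseline value (within-subject SD
#' `within_sd`) plus a `shift` (log2 units) applied to the response set.
#' Presence patterns persist within subject, so a zero `shift` gives an
#' exchangeable pre/post null.
#'
#' @param n_subjects number of paired subjects.
#' @param n_sgbs SGB universe size.
#' @param response_set SGB ids shifted at endpoint (subset of universe).
#' @param shift log2 fold change planted at endpoint.
#' @param seed RNG seed.
#' @param within_sd within-subject log SD of the endpoint re-draw.
#' @return list with `baseline`, `endpoint` ([abundance_table]s), `meta`
#'   (sample, subject and timepoint labels) and `pairing` (subject ->
#'   baseline/endpoint sample ids).
#' @export
generate_paired_intervention <- function(n_subjects, n_sgbs = 150,
                                         response_set = character(),
                                         shift = 0, seed,
                                         within_sd = 0.5) {
  if (missing(seed)) stop("seed is mandatory")
  sgbs <- sgb_universe(n_sgbs)
  if (!all(response_set %in% sgbs))
    stop("response_set contains SGBs outside the universe")
  set.seed(seed + 550001L)
  presence_p <- stats::runif(n_sgbs, 0.15, 0.9)
  meanlog <- stats::rnorm(n_sgbs, 0, 1)
  set.seed(seed)
  subj <- sprintf("SUBJ%04d", seq_len(n_subjects))
  ids_b <- paste0(subj, "_B")
  ids_e <- paste0(subj, "_E")
  base <- .sim_abundance(n_subjects, presence_p, meanlog, 1, ids_b, sgbs)
  delta <- matrix(stats::rnorm(n_subjects * n_sgbs, 0, within_sd),
                  n_subjects, n_sgbs)
  logab_e <- base$logab + delta
  logab_e[, match(response_set, sgbs)] <-
    logab_e[, match(response_set, sgbs), drop = FALSE] + shift * log(2)
  raw_e <- ifelse(base$pres, exp(logab_e), 0)
  totals <- stats::runif(n_subjects, 0.85, 1)
  rs <- rowSums(raw_e)
  vals_e <- raw_e * ifelse(rs > 0, totals / rs, 0)
  dimnames(vals_e) <- list(ids_e, sgbs)
  cov <- .sim_covariates(n_subjects)
  meta <- data.frame(
    sample_id = c(ids_b, ids_e),
    cohort_id = "intervention",
    subject_id = rep(subj, 2),
    sex = rep(cov$sex, 2), age = rep(cov$age, 2), bmi = rep(cov$bmi, 2),
    timepoint = rep(c("baseline", "endpoint"), each = n_subjects),
    stringsAsFactors = FALSE)
  list(baseline = abundance_table(base$values),
       endpoint = abundance_table(vals_e),
       meta = meta,
       pairing = data.frame(subject_id = subj, baseline = ids_b,
                            endpoint = ids_e, stringsAsFactors = FALSE))
}
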