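#' Default pipeline configuration
#'
#' A small end-to-end configuration: simulate a multi-cohort collection
#' with planted truth, build the health/diet ranking, score the samples,
#' and meta-analyse a matching synthetic case-control collection.
#'
#' @param stages subset of `c("simulate", "rank", "score", "meta")`.
#' @return nested configuration list accepted by [run_pipeline].
#' @export
default_pipeline_config <- function(stages = c("simulate", "rank",
                                               "score", "meta")) {
  list(stages = stages,
       simulate = list(n_cohorts = 2, n_samples = 150, n_sgbs = 80,
                       n_favourable = 8, n_unfavourable = 8,
                       effect_size = 0.5),
       rank = list(prevalence = 0.2, min_cohorts = 2,
                   covariates = c("sex", "age", "bmi"), min_n = 30),
       score = list(k = 10, which = "health"),
       meta = list(n_datasets = 4, n_per_arm = 40, case_shift = 1))
}

.known_stages <- c("simulate", "rank", "score", "meta")

# named substream derivation: each stage gets a seed that depends only on
# the master seed and the stage name, so stage reordering cannot change
# results; offsets keep seeds well inside 32-bit integer range
.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 10007 * match(stage, .known_stages)) %%
               .Machine$integer.max)
}

#' Run the staged pipeline
#'
#' Executes the configured stages in dependency order
#' (simulate -> rank -> score -> meta), fanning one master seed out into
#' per-stage substreams, writing plain-text TSV/JSON artifacts under
#' `out_dir`, and returning a run manifest listing every output with its
#' md5 digest. Identical configuration and seed give byte-identical
#' TSV/JSON outputs; manifests differ only in timestamps.
#'
#' @param config configuration list, see [default_pipeline_config].
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @return the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, seed = 1) {
  if (is.null(config$stages) || length(config$stages) == 0)
    stop("configuration error at 'stages': no stages requested")
  unknown <- setdiff(config$stages, .known_stages)
  if (length(unknown) > 0)
    stop("configuration error at 'stages': unknown stage '",
         unknown[1], "'")
  stages <- .known_stages[.known_stages %in% config$stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  state <- list()

  if ("simulate" %in% stages) {
    sc <- config$simulate
    truth <- planted_truth(sgb_universe(sc$n_sgbs), sc$n_favourable,
                           sc$n_unfavourable, sc$effect_size)
    s0 <- .stage_seed(seed, "simulate")
    configs <- lapply(seq_len(sc$n_cohorts), function(i)
      cohort_sim_config(sprintf("C%02d", i), sc$n_samples, sc$n_sgbs,
                        seed = s0 + i))
    state$sim <- generate_multi_cohort(configs, truth)
    paths <- character()
    for (ch in names(state$sim$cohorts)) {
      pp <- file.path(out_dir, sprintf("profiles_%s.tsv", ch))
      mp <- file.path(out_dir, sprintf("metadata_%s.tsv", ch))
      write_merged_profiles(state$sim$cohorts[[ch]]$table, pp)
      write_sample_metadata(state$sim$cohorts[[ch]]$meta, mp)
      paths <- c(paths, pp, mp)
    }
    outputs$simulate <- paths
  }

  if ("rank" %in% stages) {
    if (is.null(state$sim)) stop("stage 'rank': missing upstream simulate output")
    rc <- config$rank
    meta_all <- do.call(rbind, lapply(state$sim$cohorts, `[[`, "meta"))
    state$ranking <- rank_species(
      tables = lapply(state$sim$cohorts, `[[`, "table"),
      markers = lapply(state$sim$cohorts, `[[`, "markers"),
      meta = meta_all, panel = state$sim$panel,
      covariates = rc$covariates, prevalence = rc$prevalence,
      min_cohorts = rc$min_cohorts, min_n = rc$min_n)
    rp <- file.path(out_dir, "ranking.tsv")
    write_ranking(state$ranking, rp)
    outputs$rank <- rp
  }

  if ("score" %in% stages) {
    if (is.null(state$ranking)) stop("stage 'score': missing upstream ranking")
    sc2 <- config$score
    scores <- do.call(rbind, lapply(names(state$sim$cohorts), function(ch) {
      s <- score_samples(state$sim$cohorts[[ch]]$table, state$ranking,
                         k = sc2$k, which = sc2$which)
      s$cohort_id <- ch
      s
    }))
    sp <- file.path(out_dir, "scores.tsv")
    out <- as.data.frame(scores)
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], function(v) sprintf("%.10g", v))
    utils::write.table(out, sp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    state$scores <- scores
    outputs$score <- sp
  }

  if ("meta" %in% stages) {
    if (is.null(state$ranking)) stop("stage 'meta': missing upstream ranking")
    mc <- config$meta
    cc <- generate_case_control_collection(
      mc$n_datasets, mc$n_per_arm, state$sim$truth,
      case_shift = mc$case_shift, seed = .stage_seed(seed, "meta"))
    ests <- lapply(cc, function(d) {
      s <- score_samples(d$table, state$ranking, k = config$score$k,
                         which = config$score$which)
      beta_to_smd(fit_group_effect(
        s$rank_sum, as.integer(d$meta$status == "case"),
        covariates = d$meta[, c("sex", "age", "bmi")]))
    })
    pooled <- paule_mandel(vapply(ests, `[[`, numeric(1), "smd"),
                           vapply(ests, `[[`, numeric(1), "smd_se")^2)
    mp <- file.path(out_dir, "meta.json")
    jsonlite::write_json(list(
      per_study = lapply(ests, function(e)
        list(beta = e$beta, se = e$se, smd = e$smd, smd_se = e$smd_se,
             n_control = e$n_control, n_case = e$n_case)),
      pooled = list(smd = pooled$pooled, se = pooled$se,
                    ci95 = pooled$ci95, tau2 = pooled$tau2, p = pooled$p)),
      mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    state$meta <- pooled
    outputs$meta <- mp
  }

  files <- unlist(outputs, use.names = FALSE)
  manifest <- list(
    config = config, seed = seed,
    package_version = as.character(utils::packageVersion("microrank")),
    stages = stages,
    outputs = lapply(outputs, function(p)
      lapply(stats::setNames(as.list(p), basename(p)),
             function(f) unname(tools::md5sum(f)))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
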