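#' Extreme-set SGBs of a ranking
#'
#' The `k` most favourably ranked SGBs (smallest final ranks) and the `k`
#' most unfavourably ranked (largest), e.g. the 50-species sets used for
#' richness and cumulative-abundance comparisons. Ties at the set boundary
#' are broken by lexicographic SGB id, so the sets are deterministic.
#'
#' @param ranking a `ranking_table`.
#' @param k set size (default 50).
#' @param which `"health"` or `"diet"` ranking.
#' @return list with `favourable` and `unfavourable` id vectors, each of
#'   length `k`, disjoint.
#' @export
extreme_sets <- function(ranking, k = 50, which = c("health", "diet")) {
  which <- match.arg(which)
  col <- paste0(which, "_rank")
  r <- ranking[[col]]
  ok <- !is.na(r)
  if (sum(ok) < 2 * k)
    stop(sprintf("fewer than 2k = %d ranked SGBs available (%d)",
                 2 * k, sum(ok)))
  ids <- ranking$sgb_id[ok]
  r <- r[ok]
  ord <- order(r, ids)
  list(favourable = ids[ord][seq_len(k)],
       unfavourable = ids[rev(ord)][seq_len(k)])
}

#' Score samples against a ranking
#'
#' Per-sample summaries of ranked-species content. Each final rank is
#' normalized to `s = 1 - 2 * rank`, mapping favourable species (rank near
#' 0) to +1 and unfavourable (rank near 1) to -1, so healthier microbiomes
#' get higher scores; the convention is recorded in the
#' `"normalization"` attribute. `rank_sum` sums `s` over ranked SGBs
#' present in the sample (abundance strictly > 0); `weighted_rank_sum`
#' weights each term by the arcsine square-root of the SGB's relative
#' abundance. `fav_cum`/`unfav_cum` are the cumulative abundances of the
#' `k`-extreme sets and their arcsine square-root transforms;
#' `fav_count`/`unfav_count` the number of set members present.
#'
#' @param table an [abundance_table].
#' @param ranking a `ranking_table`.
#' @param k extreme-set size (default 50).
#' @param which `"health"` or `"diet"` ranking.
#' @return data.frame, one row per sample, class `score_report`.
#' @export
score_samples <- function(table, ranking, k = 50,
                          which = c("health", "diet")) {
  which <- match.arg(which)
  col <- paste0(which, "_rank")
  ranked <- ranking[!is.na(ranking[[col]]), c("sgb_id", col)]
  shared <- intersect(colnames(table), ranked$sgb_id)
  empty <- length(shared) == 0
  if (empty) warning("no ranked SGBs present in the abundance table")
  sets <- if (!empty && nrow(ranked) >= 2 * k) {
    extreme_sets(ranking, k, which)
  } else {
    if (!empty) warning("fewer than 2k ranked SGBs; extreme sets empty")
    list(favourable = character(), unfavourable = character())
  }
  m <- unclass(table)
  s_norm <- stats::setNames(1 - 2 * ranked[[col]], ranked$sgb_id)[shared]
  sub <- m[, shared, drop = FALSE]
  pres <- sub > 0
  fav <- intersect(sets$favourable, colnames(m))
  unf <- intersect(sets$unfavourable, colnames(m))
  fav_cum <- pmin(rowSums(m[, fav, drop = FALSE]), 1)
  unfav_cum <- pmin(rowSums(m[, unf, drop = FALSE]), 1)
  out <- data.frame(
    sample_id = rownames(m),
    fav_count = as.integer(rowSums(m[, fav, drop = FALSE] > 0)),
    unfav_count = as.integer(rowSums(m[, unf, drop = FALSE] > 0)),
    fav_cum = fav_cum,
    unfav_cum = unfav_cum,
    fav_cum_asin = arcsin_sqrt(fav_cum),
    unfav_cum_asin = arcsin_sqrt(unfav_cum),
    rank_sum = as.numeric(pres %*% s_norm),
    weighted_rank_sum = as.numeric((pres * arcsin_sqrt(sub)) %*% s_norm),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "normalization") <- "s = 1 - 2*rank; favourable species score +"
  attr(out, "empty_intersection") <- empty
  class(out) <- c("score_report", "data.frame")
  out
}
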