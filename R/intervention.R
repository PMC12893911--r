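#' Paired pre/post differential abundance
#'
#' Tests each SGB prevalent enough at both timepoints (prevalence >=
#' `min_prev`, default 10%) with a two-sided Wilcoxon signed-rank test on
#' the paired abundances. Zero within-pair differences are dropped; the
#' exact null distribution is used for up to 25 informative pairs with
#' untied absolute differences, otherwise the normal approximation with
#' tie correction. The effect size is the log2 ratio of mean relative
#' abundance at endpoint over baseline (with a small pseudocount guard for
#' degenerate zero means). Benjamini-Hochberg Q values are attached via
#' [bh_fdr].
#'
#' @param baseline,endpoint [abundance_table]s over the same SGBs.
#' @param pairing data.frame with columns `baseline` and `endpoint` giving
#'   the paired sample ids (one row per subject).
#' @param min_prev prevalence gate applied at both timepoints.
#' @param pseudocount guard added to a zero mean before the ratio.
#' @return data.frame of `intervention_record`s: `sgb_id`, `prev_base`,
#'   `prev_end`, `mean_base`, `mean_end`, `log2_ratio`, `p`, `q`,
#'   `direction`.
#' @export
prepost_differential <- function(baseline, endpoint, pairing,
                                 min_prev = 0.10, pseudocount = 1e-8) {
  if (!all(c("baseline", "endpoint") %in% names(pairing)))
    stop("pairing needs 'baseline' and 'endpoint' columns")
  miss_b <- setdiff(pairing$baseline, rownames(baseline))
  miss_e <- setdiff(pairing$endpoint, rownames(endpoint))
  if (length(miss_b) + length(miss_e) > 0)
    stop("unpaired subjects; missing sample ids: ",
         paste(c(miss_b, miss_e), collapse = ", "))
  sgbs <- intersect(colnames(baseline), colnames(endpoint))
  if (length(sgbs) == 0) stop("no shared SGBs between timepoints")
  B <- unclass(baseline)[pairing$baseline, sgbs, drop = FALSE]
  E <- unclass(endpoint)[pairing$endpoint, sgbs, drop = FALSE]
  prev_b <- colMeans(B > 0)
  prev_e <- colMeans(E > 0)
  keep <- prev_b >= min_prev & prev_e >= min_prev
  sgbs <- sgbs[keep]
  res <- lapply(sgbs, function(s) {
    b <- B[, s]; e <- E[, s]
    d <- e - b
    inf <- d != 0
    p <- if (sum(inf) == 0) 1 else {
      exact <- sum(inf) <= 25 && !any(duplicated(abs(d[inf])))
      suppressWarnings(stats::wilcox.test(e, b, paired = TRUE,
                                          exact = exact)$p.value)
    }
    mb <- mean(b); me <- mean(e)
    lr <- log2(max(me, pseudocount) / max(mb, pseudocount))
    data.frame(sgb_id = s,
               prev_base = prev_b[[s]], prev_end = prev_e[[s]],
               mean_base = mb, mean_end = me, log2_ratio = lr,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(sgb_id = character(), prev_base = numeric(),
                      prev_end = numeric(), mean_base = numeric(),
                      mean_end = numeric(), log2_ratio = numeric(),
                      p = numeric(), q = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  } else {
    out$q <- bh_fdr(out$p)
    out$direction <- ifelse(out$log2_ratio >= 0, "increase", "decrease")
    rownames(out) <- NULL
  }
  class(out) <- c("intervention_record", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values (Q values) controlling the FDR, in the input
#' order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return Q values, same order and length.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Rank-shift enrichment of intervention responders
#'
#' Splits the significantly changing SGBs (Q below `q_threshold`) by
#' direction of change and compares their final ranks with a two-sided
#' Mann-Whitney U test (average ties): if diet improvement favours
#' well-ranked species, SGBs increasing in abundance should carry more
#' favourable (smaller) ranks than decreasing ones.
#'
#' @param records output of [prepost_differential].
#' @param ranking a `ranking_table`.
#' @param q_threshold significance gate on Q (default 0.01).
#' @param which `"health"` or `"diet"` ranking.
#' @return list: `U`, `p`, `median_increase`, `median_decrease`,
#'   `n_increase`, `n_decrease`, `n_unranked`; `p` is `NA` with an
#'   `insufficient` flag when either side has fewer than 3 ranked SGBs.
#' @export
rank_shift_enrichment <- function(records, ranking, q_threshold = 0.01,
                                  which = c("health", "diet")) {
  which <- match.arg(which)
  col <- paste0(which, "_rank")
  sig <- records[records$q < q_threshold, , drop = FALSE]
  r <- ranking[[col]][match(sig$sgb_id, ranking$sgb_id)]
  n_unranked <- sum(is.na(r))
  inc <- r[sig$direction == "increase" & !is.na(r)]
  dec <- r[sig$direction == "decrease" & !is.na(r)]
  if (length(inc) < 3 || length(dec) < 3) {
    return(list(U = NA_real_, p = NA_real_,
                median_increase = stats::median(inc),
                median_decrease = stats::median(dec),
                n_increase = length(inc), n_decrease = length(dec),
                n_unranked = n_unranked, insufficient = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(inc, dec, exact =
    !any(duplicated(c(inc, dec)))))
  list(U = unname(wt$statistic), p = wt$p.value,
       median_increase = stats::median(inc),
       median_decrease = stats::median(dec),
       n_increase = length(inc), n_decrease = length(dec),
       n_unranked = n_unranked, insufficient = FALSE)
}
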