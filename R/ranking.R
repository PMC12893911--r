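#' Define a marker panel
#'
#' A marker panel names the host markers used for ranking, assigns each to
#' one category, and fixes its health direction: `+1` when a higher value
#' indicates better health (e.g. HDL, insulin sensitivity, healthy-diet
#' indices), `-1` when a higher value is less healthy (e.g. triglycerides,
#' inflammation). The `personal`, `fasting` and `postprandial` categories
#' feed the health ranking; `dietary` feeds the diet ranking.
#'
#' @param marker character vector of unique marker names.
#' @param category one of `personal`, `fasting`, `postprandial`, `dietary`
#'   per marker.
#' @param direction `+1` or `-1` per marker.
#' @return a `marker_panel` data.frame.
#' @export
marker_panel <- function(marker, category, direction) {
  category <- match.arg(category, c("personal", "fasting", "postprandial",
                                    "dietary"), several.ok = TRUE)
  if (anyDuplicated(marker)) stop("marker names must be unique")
  if (length(category) == 1) category <- rep(category, length(marker))
  if (length(direction) == 1) direction <- rep(direction, length(marker))
  if (length(category) != length(marker) || length(direction) != length(marker))
    stop("category and direction must match the number of markers")
  if (!all(direction %in% c(-1, 1))) stop("direction must be +1 or -1")
  structure(data.frame(marker = as.character(marker), category = category,
                       direction = as.integer(direction),
                       stringsAsFactors = FALSE),
            class = c("marker_panel", "data.frame"))
}

health_categories <- c("personal", "fasting", "postprandial")

# average-tie ranks of the complete cases of a numeric vector
.tie_rank <- function(v) rank(v, ties.method = "average")

#' Partial Spearman correlation
#'
#' Rank correlation between `x` and `y` after removing the linear effect of
#' covariates on the ranks: all variables are average-tie rank transformed,
#' `x` and `y` ranks are each residualized on the covariate ranks plus an
#' intercept by least squares, and the Pearson correlation of the residuals
#' is returned. With no covariates this reduces exactly to plain Spearman.
#' The p-value uses the t distribution with `n - 2 - k` degrees of freedom
#' (k covariates). Zeros in `x` are ordinary tied values and are retained.
#'
#' @param x,y numeric vectors on a shared sample index.
#' @param covariates optional numeric matrix or data.frame of covariates.
#' @param min_n minimum complete cases; defaults to `max(8, k + 3)`.
#' @return list with `rho`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, covariates = NULL, min_n = NULL) {
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(x))
      stop("covariates must have one row per observation")
  }
  if (length(x) != length(y)) stop("x and y lengths differ")
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (is.null(min_n)) min_n <- max(8L, k + 3L)
  cc <- !is.na(x) & !is.na(y)
  if (k > 0) cc <- cc & stats::complete.cases(covariates)
  n <- sum(cc)
  if (n < min_n) stop(sprintf("insufficient complete cases (%d < %d)", n, min_n))
  rx <- .tie_rank(x[cc]); ry <- .tie_rank(y[cc])
  if (length(unique(rx)) < 2 || length(unique(ry)) < 2)
    stop("undefined correlation: constant variable after deletion")
  if (k > 0) {
    rz <- apply(covariates[cc, , drop = FALSE], 2, .tie_rank)
    q <- qr(cbind(1, rz))
    rx <- qr.resid(q, rx)
    ry <- qr.resid(q, ry)
    if (sum(rx^2) < 1e-12 || sum(ry^2) < 1e-12)
      stop("undefined correlation: variable fully explained by covariates")
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2 - k
  tstat <- rho * sqrt(df / max(1 - rho^2, 1e-300))
  p <- if (df > 0) 2 * stats::pt(-abs(tstat), df) else NA_real_
  list(rho = rho, p = p, n = n)
}

#' Correlate every SGB against every marker
#'
#' Computes the covariate-adjusted partial Spearman correlation for each
#' (SGB, marker) pair, with pairwise-complete deletion per marker. Cells
#' whose complete-case count falls below `min_n` are returned as missing
#' (`NA`) and are treated downstream as "not ranked in this cohort".
#'
#' @param table a prevalence-filtered [abundance_table].
#' @param markers numeric matrix of marker values, samples in rows (named),
#'   markers in columns.
#' @param covariates data.frame/matrix of adjustment covariates with
#'   rownames matching sample ids (typically sex, age, BMI), or `NULL`.
#' @param min_n minimum complete cases per cell (default 30).
#' @return long data.frame `sgb_id`, `marker`, `rho`, `p`, `n`, class
#'   `correlation_frame`.
#' @export
correlate_all <- function(table, markers, covariates = NULL, min_n = 30) {
  markers <- as.matrix(markers)
  shared <- intersect(rownames(table), rownames(markers))
  if (length(shared) == 0) stop("no overlapping samples between table and markers")
  ab <- unclass(table)[shared, , drop = FALSE]
  mk <- markers[shared, , drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates))) stop("covariates need sample rownames")
    covariates <- covariates[shared, , drop = FALSE]
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  out <- vector("list", ncol(mk))
  for (j in seq_len(ncol(mk))) {
    y <- mk[, j]
    cc <- !is.na(y)
    if (k > 0) cc <- cc & stats::complete.cases(covariates)
    n <- sum(cc)
    res <- data.frame(sgb_id = colnames(ab), marker = colnames(mk)[j],
                      rho = NA_real_, p = NA_real_, n = n,
                      stringsAsFactors = FALSE)
    if (n >= max(min_n, k + 3)) {
      ry <- .tie_rank(y[cc])
      rx <- apply(ab[cc, , drop = FALSE], 2, .tie_rank)
      if (k > 0) {
        q <- qr(cbind(1, apply(covariates[cc, , drop = FALSE], 2, .tie_rank)))
        ry <- qr.resid(q, ry)
        rx <- qr.resid(q, rx)
      } else {
        ry <- ry - mean(ry)
        rx <- sweep(rx, 2, colMeans(rx))
      }
      ssx <- colSums(rx^2)
      rho <- as.numeric(crossprod(rx, ry)) / sqrt(ssx * sum(ry^2))
      rho[ssx < 1e-12 | sum(ry^2) < 1e-12] <- NA
      df <- n - 2 - k
      tstat <- rho * sqrt(df / pmax(1 - rho^2, 1e-300))
      res$rho <- rho
      res$p <- 2 * stats::pt(-abs(tstat), df)
    }
    out[[j]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("correlation_frame", "data.frame")
  out
}

#' Per-marker percentile ranks
#'
#' Orients each correlation by the marker's health direction
#' (`oriented = direction * rho`), sorts SGBs by descending oriented score,
#' and converts positions to percentiles: average-tie fractional rank
#' divided by the number of ranked SGBs, so percentiles lie in (0, 1\] and
#' the SGB most favourably correlated with health gets the smallest value.
#' Missing correlation cells yield missing percentiles.
#'
#' @param frame a `correlation_frame` from [correlate_all].
#' @param panel a [marker_panel] covering every marker in `frame`.
#' @return numeric matrix SGB x marker of percentiles.
#' @export
marker_percentiles <- function(frame, panel) {
  miss <- setdiff(unique(frame$marker), panel$marker)
  if (length(miss) > 0)
    stop("markers missing a panel direction: ", paste(miss, collapse = ", "))
  dir <- stats::setNames(panel$direction, panel$marker)
  sgbs <- unique(frame$sgb_id)
  mks <- unique(frame$marker)
  pct <- matrix(NA_real_, length(sgbs), length(mks),
                dimnames = list(sgbs, mks))
  for (m in mks) {
    sub <- frame[frame$marker == m, , drop = FALSE]
    oriented <- dir[[m]] * sub$rho
    ok <- !is.na(oriented)
    if (any(ok))
      pct[sub$sgb_id[ok], m] <-
        rank(-oriented[ok], ties.method = "average") / sum(ok)
  }
  pct
}

#' Build the cross-cohort health and diet ranking
#'
#' Within each cohort, marker percentiles are averaged within each category
#' (unweighted, over the markers available), the non-dietary category means
#' are averaged into a cohort-level health value, and the dietary-category
#' mean gives the cohort diet value. The final health-rank and diet-rank
#' are the unweighted means of the cohort values over the cohorts in which
#' the SGB was ranked; SGBs ranked in fewer than `min_cohorts` cohorts
#' carry no final value for that ranking.
#'
#' @param percentiles named list (one element per cohort) of SGB x marker
#'   percentile matrices from [marker_percentiles].
#' @param panel the [marker_panel].
#' @param min_cohorts retention threshold (default 2).
#' @return a `ranking_table` data.frame: `sgb_id`, `health_rank`,
#'   `diet_rank`, `n_cohorts_health`, `n_cohorts_diet`, then one column per
#'   (cohort, category) mean percentile and per cohort health mean.
#' @export
build_ranking <- function(percentiles, panel, min_cohorts = 2) {
  if (length(percentiles) < 1) stop("at least one cohort is required")
  if (is.null(names(percentiles)) || anyDuplicated(names(percentiles)))
    stop("percentiles must be a uniquely named list of cohort matrices")
  stopifnot(min_cohorts >= 1)
  sgbs <- sort(unique(unlist(lapply(percentiles, rownames))))
  cohorts <- names(percentiles)
  cat_of <- stats::setNames(panel$category, panel$marker)
  health_mat <- matrix(NA_real_, length(sgbs), length(cohorts),
                       dimnames = list(sgbs, cohorts))
  diet_mat <- health_mat
  extra <- list()
  for (ch in cohorts) {
    pct <- percentiles[[ch]]
    cats_here <- intersect(c(health_categories, "dietary"),
                           unique(cat_of[colnames(pct)]))
    cat_means <- vapply(cats_here, function(cg) {
      cols <- colnames(pct)[cat_of[colnames(pct)] == cg]
      rowMeans(pct[, cols, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(pct)))
    cat_means <- matrix(cat_means, nrow = nrow(pct),
                        dimnames = list(rownames(pct), cats_here))
    cat_means[is.nan(cat_means)] <- NA
    for (cg in cats_here)
      extra[[paste(ch, cg, sep = ".")]] <-
        stats::setNames(cat_means[, cg], rownames(pct))
    hc <- intersect(health_categories, cats_here)
    if (length(hc) > 0) {
      hm <- rowMeans(cat_means[, hc, drop = FALSE], na.rm = TRUE)
      hm[is.nan(hm)] <- NA
      health_mat[rownames(pct), ch] <- hm
    }
    if ("dietary" %in% cats_here)
      diet_mat[rownames(pct), ch] <- cat_means[, "dietary"]
  }
  n_h <- rowSums(!is.na(health_mat))
  n_d <- rowSums(!is.na(diet_mat))
  health_rank <- ifelse(n_h >= min_cohorts,
                        rowMeans(health_mat, na.rm = TRUE), NA)
  diet_rank <- ifelse(n_d >= min_cohorts,
                      rowMeans(diet_mat, na.rm = TRUE), NA)
  out <- data.frame(sgb_id = sgbs, health_rank = health_rank,
                    diet_rank = diet_rank,
                    n_cohorts_health = as.integer(n_h),
                    n_cohorts_diet = as.integer(n_d),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (ch in cohorts)
    out[[paste0("health_mean.", ch)]] <- health_mat[out$sgb_id, ch]
  for (nm in names(extra))
    out[[paste0("pct.", nm)]] <- extra[[nm]][out$sgb_id]
  out <- out[n_h > 0 | n_d > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' One-call species ranking across cohorts
#'
#' Convenience wrapper running the full ranking pipeline on per-cohort
#' inputs: prevalence filter per cohort, covariate-adjusted partial
#' Spearman correlations, per-marker percentiles, and cross-cohort
#' aggregation via [build_ranking].
#'
#' @param tables named list of per-cohort [abundance_table]s.
#' @param markers named list of per-cohort marker matrices.
#' @param meta metadata data.frame covering all samples (`sample_id` plus
#'   the covariate columns).
#' @param covariates character vector of covariate column names
#'   (default `c("sex", "age", "bmi")`; drop `"bmi"` for the
#'   BMI-unadjusted variant).
#' @param panel the [marker_panel].
#' @param prevalence prevalence threshold per cohort (default 0.2).
#' @param min_cohorts retention threshold (default 2).
#' @param min_n minimum complete cases per correlation cell (default 30).
#' @return a `ranking_table`.
#' @export
rank_species <- function(tables, markers, meta, panel,
                         covariates = c("sex", "age", "bmi"),
                         prevalence = 0.2, min_cohorts = 2, min_n = 30) {
  stopifnot(identical(names(tables), names(markers)))
  pcts <- lapply(names(tables), function(ch) {
    tab <- prevalence_filter(tables[[ch]], prevalence)
    cov <- NULL
    if (length(covariates) > 0) {
      idx <- match(rownames(tab), meta$sample_id)
      cov <- as.matrix(meta[idx, covariates, drop = FALSE])
      storage.mode(cov) <- "double"
      rownames(cov) <- rownames(tab)
    }
    marker_percentiles(correlate_all(tab, markers[[ch]], cov, min_n = min_n),
                       panel)
  })
  names(pcts) <- names(tables)
  build_ranking(pcts, panel, min_cohorts = min_cohorts)
}

#' Intraclass correlation of rankings across cohorts
#'
#' Agreement of per-cohort rank values treating SGBs as targets and cohorts
#' as raters: single-measurement, absolute-agreement ICC under the two-way
#' random-effects model, computed from the mean squares of the two-way
#' ANOVA decomposition. Rows with any missing value are dropped.
#'
#' @param rank_matrix numeric matrix, SGBs in rows, cohorts in columns.
#' @return list with `icc`, `n` (complete rows), `k` (columns).
#' @export
icc_agreement <- function(rank_matrix) {
  rank_matrix <- as.matrix(rank_matrix)
  if (ncol(rank_matrix) < 2) stop("at least two columns are required")
  rank_matrix <- rank_matrix[stats::complete.cases(rank_matrix), , drop = FALSE]
  n <- nrow(rank_matrix); k <- ncol(rank_matrix)
  if (n < 3) stop("insufficient data: fewer than 3 complete rows")
  row_m <- rowMeans(rank_matrix); col_m <- colMeans(rank_matrix)
  grand <- mean(rank_matrix)
  msr <- k * sum((row_m - grand)^2) / (n - 1)        # between targets
  msc <- n * sum((col_m - grand)^2) / (k - 1)        # between raters
  sse <- sum((rank_matrix - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, n = n, k = k)
}

#' Spearman concordance of two rankings
#'
#' Plain Spearman correlation (average ties) of two named rank vectors on
#' their shared SGB ids.
#'
#' @param rank_a,rank_b named numeric vectors of final ranks.
#' @param min_shared minimum shared ids (default 8).
#' @return list with `rho`, `n_shared`.
#' @export
rank_concordance <- function(rank_a, rank_b, min_shared = 8) {
  shared <- intersect(names(rank_a)[!is.na(rank_a)],
                      names(rank_b)[!is.na(rank_b)])
  if (length(shared) < min_shared)
    stop(sprintf("insufficient shared SGBs (%d < %d)",
                 length(shared), min_shared))
  rho <- stats::cor(rank_a[shared], rank_b[shared], method = "spearman")
  list(rho = as.numeric(rho), n_shared = length(shared))
}

#' Write a ranking table as TSV
#' @param ranking a `ranking_table`.
#' @param path output path.
#' @export
write_ranking <- function(ranking, path) {
  out <- as.data.frame(ranking)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "sgb_id" &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(v) ifelse(is.na(v), "NA",
                                                  sprintf("%.10g", v)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranking table
#'
#' Accepts both this package's full TSV and a minimal published table with
#' at least `sgb_id` and one of `health_rank` / `diet_rank`.
#'
#' @param path path to a ranking TSV.
#' @return a `ranking_table`.
#' @export
read_ranking <- function(path) {
  out <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sgb_id" %in% names(out) ||
      !any(c("health_rank", "diet_rank") %in% names(out)))
    stop("ranking table needs sgb_id and health_rank or diet_rank")
  class(out) <- c("ranking_table", "data.frame")
  out
}
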