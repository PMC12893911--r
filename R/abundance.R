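#' Construct an abundance table
#'
#' The central measurement object: a sample x SGB matrix of relative
#' abundances expressed as fractions in \[0, 1\]. Per-sample sums may fall
#' short of 1 (unclassified reads are not carried as a row) but may not
#' exceed it beyond numerical noise.
#'
#' @param values numeric matrix, samples in rows, SGBs in columns.
#' @param sample_ids,sgb_ids optional identifier vectors; default to the
#'   dimnames of `values`.
#' @param taxonomy optional character vector of full taxonomy strings, one
#'   per SGB, carried as an attribute and written back on output.
#' @return an `abundance_table`: the validated matrix with class attribute.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            sgb_ids = colnames(values), taxonomy = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(sgb_ids))
    stop("sample_ids and sgb_ids are required (or set dimnames)")
  if (length(sample_ids) != nrow(values) || length(sgb_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(sgb_ids)) stop("duplicate SGB ids")
  if (anyNA(values)) stop("abundance values must not be missing")
  if (any(values < 0)) stop("abundance values must be non-negative")
  if (ncol(values) > 0 && nrow(values) > 0 && any(rowSums(values) > 1 + 1e-6))
    stop("per-sample abundance fractions sum to more than 1")
  dimnames(values) <- list(as.character(sample_ids), as.character(sgb_ids))
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != ncol(values))
      stop("taxonomy length must match the number of SGBs")
    attr(values, "taxonomy") <- as.character(taxonomy)
  }
  class(values) <- c("abundance_table", "matrix", "array")
  values
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d SGBs\n", nrow(x), ncol(x)))
  if (nrow(x) > 0 && ncol(x) > 0)
    cat(sprintf("  per-sample total: %.3f-%.3f; overall prevalence median %.2f\n",
                min(rowSums(x)), max(rowSums(x)),
                stats::median(colMeans(x > 0))))
  invisible(x)
}

#' @export
`[.abundance_table` <- function(x, i, j, ..., drop = FALSE) {
  tax <- attr(x, "taxonomy")
  y <- NextMethod(drop = FALSE)
  if (!is.null(tax)) {
    keep <- if (missing(j)) seq_along(tax) else seq_along(tax)[j]
    attr(y, "taxonomy") <- tax[keep]
  }
  class(y) <- c("abundance_table", "matrix", "array")
  y
}

sample_ids <- function(x) rownames(x)
sgb_ids <- function(x) colnames(x)

#' Read a merged taxonomic profile table
#'
#' Parses the merged-table dialect produced by MetaPhlAn-style profilers:
#' first column is the clade name (pipe-separated taxonomy ending, at
#' species-bin level, in a `t__SGB...` component), an optional second
#' column of NCBI taxonomy ids is tolerated and ignored, and one numeric
#' column per sample holds relative abundances on the 0-100 percent scale.
#' Only rows terminating at the requested level are retained and values are
#' converted to fractions. `_group`-suffixed SGB labels (merged bins whose
#' marker genes cannot be separated) are preserved verbatim.
#'
#' @param path path to a tab-separated profile table.
#' @param level taxonomic level to retain; only `"SGB"` (clades containing
#'   a `t__` component) is currently supported.
#' @return an [abundance_table] with taxonomy strings attached.
#' @export
read_merged_profiles <- function(path, level = "SGB") {
  level <- match.arg(level, "SGB")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 2) stop("malformed header: need a clade column and at least one sample")
  clade <- as.character(raw[[1]])
  raw <- raw[, -1, drop = FALSE]
  # tolerate an NCBI id column: non-abundance, recognisable by name
  if (grepl("taxid|NCBI", names(raw)[1], ignore.case = TRUE))
    raw <- raw[, -1, drop = FALSE]
  if (ncol(raw) == 0) stop("malformed header: no sample columns")
  if (!all(vapply(raw, is.numeric, logical(1))))
    stop("malformed table: non-numeric sample column")
  keep <- grepl("t__", clade)
  if (!any(keep)) {
    warning("no rows at the requested level; returning an empty table")
    return(abundance_table(matrix(0, nrow = ncol(raw), ncol = 0),
                           sample_ids = names(raw), sgb_ids = character()))
  }
  vals <- as.matrix(raw[keep, , drop = FALSE])
  if (any(vals < 0)) stop("negative abundance value")
  clade <- clade[keep]
  sgb <- sub("^.*t__", "", clade)
  if (anyDuplicated(sgb)) stop("duplicate SGB id in profile table")
  abundance_table(t(vals) / 100, sample_ids = names(raw), sgb_ids = sgb,
                  taxonomy = clade)
}

#' Write an abundance table in the merged-profile dialect
#'
#' Inverse of [read_merged_profiles]: fractions are written back as
#' percentages with the taxonomy string (or bare SGB id) as first column.
#' Round-trips values to better than 1e-9.
#'
#' @param x an [abundance_table].
#' @param path output path.
#' @export
write_merged_profiles <- function(x, path) {
  tax <- attr(x, "taxonomy")
  if (is.null(tax)) tax <- paste0("t__", colnames(x))
  out <- data.frame(clade_name = tax, check.names = FALSE,
                    stringsAsFactors = FALSE)
  vals <- t(unclass(x)) * 100
  for (i in seq_len(nrow(x))) out[[rownames(x)[i]]] <- sprintf("%.10g", vals[, i])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Prevalence filter
#'
#' Retains SGBs whose prevalence (fraction of samples with abundance
#' strictly greater than zero) is strictly greater than `threshold`; the
#' default reproduces the "greater than 20% prevalence" rule used to define
#' the non-rare species set.
#'
#' @param x an [abundance_table].
#' @param threshold prevalence threshold in \[0, 1).
#' @return the filtered [abundance_table]; sample set unchanged.
#' @export
prevalence_filter <- function(x, threshold = 0.2) {
  if (!inherits(x, "abundance_table")) stop("x must be an abundance_table")
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty abundance table")
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  prev <- colMeans(unclass(x) > 0)
  x[, prev > threshold, drop = FALSE]
}

#' Arcsine square-root transform
#'
#' Variance-stabilising transform for proportions, applied to relative
#' abundances before linear modelling. Values marginally above 1 (up to
#' 1 + 1e-6, numerical residue of compositional sums) are clamped to 1.
#'
#' @param x numeric vector or matrix of fractions in \[0, 1\].
#' @return `asin(sqrt(x))`, in \[0, pi/2\].
#' @export
arcsin_sqrt <- function(x) {
  if (any(x < 0, na.rm = TRUE) || any(x > 1 + 1e-6, na.rm = TRUE))
    stop("arcsin_sqrt is defined on [0, 1]")
  asin(sqrt(pmin(x, 1)))
}

#' Per-sample alpha diversity
#'
#' Richness is the count of SGBs with non-zero abundance; Shannon entropy
#' (natural log) is computed on the non-zero fractions renormalized to sum
#' to one, so it is invariant to the unclassified remainder. An all-zero
#' sample gets richness 0 and entropy 0.
#'
#' @param x an [abundance_table].
#' @return data.frame with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(x) {
  if (!inherits(x, "abundance_table")) stop("x must be an abundance_table")
  if (nrow(x) == 0) stop("empty abundance table")
  m <- unclass(x)
  shannon <- apply(m, 1, function(v) {
    v <- v[v > 0]
    if (length(v) == 0) return(0)
    p <- v / sum(v)
    -sum(p * log(p))
  })
  data.frame(sample_id = rownames(m),
             richness = as.integer(rowSums(m > 0)),
             shannon = as.numeric(shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' BMI category labels
#'
#' Half-open WHO-style intervals: healthy weight \[18.5, 25), overweight
#' \[25, 30), obese \[30, Inf). Underweight values are rejected; callers
#' exclude BMI < 18.5 at cohort selection.
#'
#' @param bmi numeric vector, kg/m^2.
#' @param breaks strictly increasing category edges.
#' @return factor with levels `healthy weight`, `overweight`, `obese`.
#' @export
bmi_category <- function(bmi, breaks = c(18.5, 25, 30)) {
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  if (any(bmi < breaks[1], na.rm = TRUE))
    stop(sprintf("BMI below %.1f is out of range (underweight excluded upstream)", breaks[1]))
  cut(bmi, c(breaks, Inf), right = FALSE,
      labels = c("healthy weight", "overweight", "obese"))
}

#' Cohort selection rules
#'
#' Container for the eligibility thresholds applied to public cohorts:
#' minimum age, minimum BMI (underweight excluded), minimum cohort size,
#' and the minimum per-arm size for a between-group stratum.
#'
#' @param min_age minimum participant age in years.
#' @param min_bmi minimum BMI in kg/m^2.
#' @param min_cohort_n minimum eligible samples for a cohort to be kept.
#' @param min_stratum_n minimum per-arm size within a tested stratum.
#' @param bmi_breaks BMI category edges passed to [bmi_category].
#' @return a `cohort_rules` list.
#' @export
cohort_rules <- function(min_age = 16, min_bmi = 18.5, min_cohort_n = 30,
                         min_stratum_n = 15, bmi_breaks = c(18.5, 25, 30)) {
  stopifnot(min_cohort_n >= 1, min_stratum_n >= 1, all(diff(bmi_breaks) > 0))
  structure(list(min_age = min_age, min_bmi = min_bmi,
                 min_cohort_n = as.integer(min_cohort_n),
                 min_stratum_n = as.integer(min_stratum_n),
                 bmi_breaks = bmi_breaks),
            class = "cohort_rules")
}

#' Select eligible public cohorts and comparison strata
#'
#' Applies the sample-level eligibility rules (age, BMI, sex availability),
#' drops cohorts with fewer eligible samples than `min_cohort_n`, and
#' enumerates the testable strata: for `mode = "bmi-comparison"` every
#' (cohort, BMI-category pair) with both arms at least `min_stratum_n`; for
#' `mode = "case-control"` every cohort with both control and case arms at
#' least `min_stratum_n`.
#'
#' @param meta sample metadata data.frame with columns `sample_id`,
#'   `cohort_id`, `sex`, `age`, `bmi` (and `status` for case-control mode).
#' @param rules a [cohort_rules] object.
#' @param mode `"bmi-comparison"` or `"case-control"`.
#' @return data.frame of strata (cohort, arm labels, arm sizes) with the
#'   vector of retained sample ids in attribute `"samples"`.
#' @export
select_public_cohorts <- function(meta, rules = cohort_rules(),
                                  mode = c("bmi-comparison", "case-control")) {
  mode <- match.arg(mode)
  need <- c("sample_id", "cohort_id", "sex", "age", "bmi")
  if (!all(need %in% names(meta)))
    stop("metadata must contain: ", paste(need, collapse = ", "))
  ok <- !is.na(meta$sex) & !is.na(meta$age) & meta$age >= rules$min_age &
    !is.na(meta$bmi) & meta$bmi >= rules$min_bmi
  meta <- meta[ok, , drop = FALSE]
  keep_cohorts <- names(which(table(meta$cohort_id) >= rules$min_cohort_n))
  meta <- meta[meta$cohort_id %in% keep_cohorts, , drop = FALSE]
  empty <- data.frame(cohort_id = character(), group_a = character(),
                      group_b = character(), n_a = integer(), n_b = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(meta) == 0) {
    warning("no samples pass the cohort selection rules")
    attr(empty, "samples") <- character()
    return(empty)
  }
  strata <- empty
  if (mode == "bmi-comparison") {
    meta$bmi_cat <- as.character(bmi_category(meta$bmi, rules$bmi_breaks))
    lev <- c("healthy weight", "overweight", "obese")
    for (ch in unique(meta$cohort_id)) {
      cnt <- table(factor(meta$bmi_cat[meta$cohort_id == ch], levels = lev))
      for (i in 1:2) for (j in (i + 1):3) {
        if (cnt[i] >= rules$min_stratum_n && cnt[j] >= rules$min_stratum_n)
          strata <- rbind(strata, data.frame(
            cohort_id = ch, group_a = lev[i], group_b = lev[j],
            n_a = as.integer(cnt[i]), n_b = as.integer(cnt[j]),
            stringsAsFactors = FALSE))
      }
    }
  } else {
    if (!"status" %in% names(meta)) stop("case-control mode needs a status column")
    for (ch in unique(meta$cohort_id)) {
      st <- meta$status[meta$cohort_id == ch]
      n_ctl <- sum(st == "control", na.rm = TRUE)
      n_case <- sum(!is.na(st) & st != "control")
      if (n_ctl >= rules$min_stratum_n && n_case >= rules$min_stratum_n)
        strata <- rbind(strata, data.frame(
          cohort_id = ch, group_a = "control", group_b = "case",
          n_a = n_ctl, n_b = n_case, stringsAsFactors = FALSE))
    }
  }
  if (nrow(strata) == 0) warning("no stratum passes the per-arm size rule")
  attr(strata, "samples") <- meta$sample_id[meta$cohort_id %in% strata$cohort_id]
  strata
}

#' Read a sample metadata table
#'
#' Tab-separated with a header; required columns `sample_id`, `cohort_id`,
#' `sex`, `age`, `bmi`; optional `subject_id`, `twin_group`, `country`,
#' `sequencing_depth`, `status`, `timepoint`.
#'
#' @param path path to a metadata TSV.
#' @return data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "cohort_id", "sex", "age", "bmi")
  if (!all(need %in% names(meta)))
    stop("metadata must contain: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  meta
}

#' Write a sample metadata table
#' @param meta data.frame as returned by [read_sample_metadata].
#' @param path output path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
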