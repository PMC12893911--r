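#' Adjusted group effect from a linear model
#'
#' Ordinary least squares of an outcome on an intercept, a binary group
#' indicator and optional covariates. The reference level (coded 0) is the
#' control / lower-risk group, so a positive `beta` means a higher outcome
#' in the contrast group. The pooled within-group SD of the outcome is
#' carried for later standardization.
#'
#' @param y numeric outcome vector.
#' @param group binary labels; a factor/character is coded with its first
#'   sorted level as reference, a numeric vector must be 0/1.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return an `effect_estimate` list: `beta`, `se`, `n_control`, `n_case`,
#'   `outcome_sd`, `smd`, `smd_se` (filled by [beta_to_smd]), `d`,
#'   `covariates`.
#' @export
fit_group_effect <- function(y, group, covariates = NULL) {
  if (is.numeric(group)) {
    if (!all(group %in% c(0, 1))) stop("numeric group must be coded 0/1")
    g <- group
  } else {
    lev <- sort(unique(as.character(group)))
    if (length(lev) != 2) stop("group must have exactly two levels")
    g <- as.numeric(as.character(group) == lev[2])
  }
  X <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  cc <- !is.na(y) & stats::complete.cases(X)
  y <- y[cc]; X <- X[cc, , drop = FALSE]; g <- g[cc]
  if (sum(g == 0) < 4 || sum(g == 1) < 4)
    stop("each group needs at least 4 complete cases")
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("collinear design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (length(y) - ncol(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  v0 <- stats::var(y[g == 0]); v1 <- stats::var(y[g == 1])
  n0 <- sum(g == 0); n1 <- sum(g == 1)
  sd_pool <- sqrt(((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2))
  structure(list(beta = unname(fit$coefficients["group"]),
                 se = unname(se[2]),
                 n_control = n0, n_case = n1,
                 outcome_sd = sd_pool, smd = NA_real_, smd_se = NA_real_,
                 d = tryCatch(cohens_d(y[g == 1], y[g == 0]),
                              error = function(e) NA_real_),
                 covariates = if (is.null(covariates)) character()
                              else colnames(covariates)),
            class = "effect_estimate")
}

#' Cohen's d
#'
#' Difference of group means in pooled-SD units, with the pooled SD from
#' (n-1)-weighted within-group variances. By the usual reading, d = 0.2 is
#' small, 0.5 medium and 0.8 large.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return `(mean(a) - mean(b)) / pooled SD`.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("undefined effect size: zero pooled SD")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Convert an adjusted beta to a standardized mean difference
#'
#' Standardizes the adjusted group coefficient by the pooled within-group
#' SD of the outcome: `smd = beta / outcome_sd`, `smd_se = se /
#' outcome_sd`.
#'
#' @param estimate an `effect_estimate` from [fit_group_effect].
#' @return the estimate with `smd` and `smd_se` filled in.
#' @export
beta_to_smd <- function(estimate) {
  if (is.na(estimate$outcome_sd) || estimate$outcome_sd <= 0)
    stop("outcome SD must be positive for standardization")
  estimate$smd <- estimate$beta / estimate$outcome_sd
  estimate$smd_se <- estimate$se / estimate$outcome_sd
  estimate
}

#' Paule-Mandel random-effects meta-analysis
#'
#' Pools per-study effects with inverse-variance weights `1 / (v_i +
#' tau2)`, where the between-study variance `tau2` solves the
#' Paule-Mandel moment equation `sum w_i(tau2) (y_i - ybar(tau2))^2 =
#' k - 1`. The left side is monotone decreasing in `tau2`, so the root is
#' found by bisection on `[0, 100 * max(v)]` (tolerance 1e-8, expanded if
#' needed) and clamped to 0 when the criterion is already below `k - 1` at
#' `tau2 = 0`. Normal-theory 95% CI.
#'
#' @param effects per-study effect estimates.
#' @param variances per-study sampling variances (positive).
#' @return a `meta_result` list: `pooled`, `se`, `ci95`, `tau2`, `p`,
#'   `method`, `weights` (normalized to sum 1), `k`.
#' @export
paule_mandel <- function(effects, variances) {
  k <- length(effects)
  if (length(variances) != k) stop("effects and variances lengths differ")
  if (any(variances <= 0)) stop("variances must be positive")
  if (k < 1) stop("no studies")
  if (k == 1) {
    warning("degenerate meta-analysis: single study passed through")
    se <- sqrt(variances)
    return(.meta_result(effects, se, 0, "paule-mandel", 1, k))
  }
  crit <- function(tau2) {
    w <- 1 / (variances + tau2)
    yb <- sum(w * effects) / sum(w)
    sum(w * (effects - yb)^2) - (k - 1)
  }
  tau2 <- 0
  if (crit(0) > 0) {
    hi <- 100 * max(variances)
    while (crit(hi) > 0 && hi < 1e12) hi <- hi * 10
    lo <- 0
    for (i in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (crit(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-8) break
    }
    tau2 <- (lo + hi) / 2
  }
  w <- 1 / (variances + tau2)
  pooled <- sum(w * effects) / sum(w)
  se <- 1 / sqrt(sum(w))
  .meta_result(pooled, se, tau2, "paule-mandel", w / sum(w), k)
}

.meta_result <- function(pooled, se, tau2, method, weights, k) {
  structure(list(pooled = pooled, se = se,
                 ci95 = c(pooled - 1.96 * se, pooled + 1.96 * se),
                 tau2 = tau2,
                 p = 2 * stats::pnorm(-abs(pooled / se)),
                 method = method, weights = weights, k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result (%s, k = %d): %.4f [%.4f, %.4f], tau2 = %.4g, p = %.3g\n",
              x$method, x$k, x$pooled, x$ci95[1], x$ci95[2], x$tau2, x$p))
  invisible(x)
}

#' Covariance of SMDs from studies sharing a control arm
#'
#' Diagonal entries are the squared SMD standard errors; for two studies
#' sharing `n_c` control samples the off-diagonal uses the standard
#' multi-arm SMD approximation `1/n_c + smd_i * smd_j / (2 * (n_i +
#' n_j))`, where `n_i` is the study's total size. A tiny diagonal jitter
#' (1e-10) is added if the result is not positive definite.
#'
#' @param estimates list of `effect_estimate`s (after [beta_to_smd]).
#' @param overlap named list mapping `"i:j"` study index pairs to the
#'   number of shared control samples.
#' @return symmetric positive-definite covariance matrix.
#' @export
shared_control_covariance <- function(estimates, overlap = list()) {
  k <- length(estimates)
  smd <- vapply(estimates, `[[`, numeric(1), "smd")
  smd_se <- vapply(estimates, `[[`, numeric(1), "smd_se")
  n_tot <- vapply(estimates, function(e) e$n_control + e$n_case, numeric(1))
  n_ctl <- vapply(estimates, `[[`, numeric(1), "n_control")
  if (anyNA(smd_se)) stop("estimates must be standardized first (beta_to_smd)")
  V <- diag(smd_se^2, k)
  for (key in names(overlap)) {
    ij <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
    if (length(ij) != 2 || anyNA(ij) || any(ij < 1 | ij > k))
      stop("overlap keys must be 'i:j' study index pairs")
    n_c <- overlap[[key]]
    if (n_c > min(n_ctl[ij])) stop("overlap exceeds a study's control size")
    covij <- 1 / n_c + smd[ij[1]] * smd[ij[2]] / (2 * (n_tot[ij[1]] + n_tot[ij[2]]))
    V[ij[1], ij[2]] <- V[ij[2], ij[1]] <- covij
  }
  if (inherits(tryCatch(chol(V), error = function(e) e), "error"))
    V <- V + diag(1e-10, k)
  if (inherits(tryCatch(chol(V), error = function(e) e), "error"))
    stop("covariance matrix is not positive definite")
  V
}

#' Pool correlated effects by generalized least squares
#'
#' Fixed-effect pooling with weights from the inverse of the full effect
#' covariance matrix: `pooled = (1' V^-1 y) / (1' V^-1 1)`, `se = (1' V^-1
#' 1)^(-1/2)`. With a diagonal covariance this reduces exactly to the
#' inverse-variance weighted mean.
#'
#' @param estimates list of `effect_estimate`s or a numeric vector of
#'   effects.
#' @param covariance covariance matrix from [shared_control_covariance].
#' @return a `meta_result` (method `"gls-shared-controls"`, `tau2 = 0`).
#' @export
pool_shared_controls <- function(estimates, covariance) {
  y <- if (is.numeric(estimates)) estimates
       else vapply(estimates, `[[`, numeric(1), "smd")
  k <- length(y)
  if (!all(dim(covariance) == k)) stop("covariance dimension mismatch")
  Vi <- tryCatch(chol2inv(chol(covariance)), error = function(e) {
    chol2inv(chol(covariance + diag(1e-10, k)))
  })
  one <- rep(1, k)
  denom <- as.numeric(one %*% Vi %*% one)
  pooled <- as.numeric(one %*% Vi %*% y) / denom
  se <- 1 / sqrt(denom)
  w <- as.numeric(Vi %*% one) / denom
  .meta_result(pooled, se, 0, "gls-shared-controls", w, k)
}

#' Exact binomial sign test
#'
#' Tests `k` successes in `n` trials against success probability 0.5.
#' The default two-sided p-value doubles the smaller exact tail, capped at
#' 1; one-sided alternatives use the single exact tail.
#'
#' @param k successes.
#' @param n trials.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return the p-value.
#' @export
binomial_sign_test <- function(k, n, alternative = c("two.sided", "greater",
                                                     "less")) {
  alternative <- match.arg(alternative)
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  switch(alternative,
         two.sided = min(1, 2 * min(lower, upper)),
         greater = upper,
         less = lower)
}

#' Country effect blocked by dataset
#'
#' Compares an outcome between two countries whose samples come from
#' multiple datasets: a linear mixed model with a random intercept per
#' dataset and fixed effects for country and sequencing depth. When each
#' country is represented by a single dataset the random intercept is not
#' identifiable and the model falls back to ordinary least squares
#' adjusted by depth, with a notice.
#'
#' @param y numeric outcome.
#' @param country binary country labels.
#' @param dataset_ids dataset identifier per sample.
#' @param depth sequencing depth per sample.
#' @return list: `beta`, `se`, `method` (`"lmm"` or `"ols"`), `n`.
#' @export
mixed_country_effect <- function(y, country, dataset_ids, depth) {
  df <- data.frame(y = y, country = factor(country),
                   dataset = factor(dataset_ids), depth = as.numeric(depth))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$country)) != 2)
    stop("country must have exactly two levels")
  per_country <- tapply(as.character(df$dataset), df$country,
                        function(d) length(unique(d)))
  if (all(per_country <= 1)) {
    message("single dataset per country: falling back to OLS adjusted by depth")
    fit <- stats::lm(y ~ country + depth, data = df)
    sm <- summary(fit)$coefficients
    return(list(beta = sm[2, 1], se = sm[2, 2], method = "ols",
                n = nrow(df)))
  }
  fit <- lme4::lmer(y ~ country + depth + (1 | dataset), data = df,
                    REML = TRUE)
  sm <- summary(fit)$coefficients
  list(beta = sm["country" %+% levels(df$country)[2], 1],
       se = sm["country" %+% levels(df$country)[2], 2],
       method = "lmm", n = nrow(df))
}

`%+%` <- function(a, b) paste0(a, b)
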