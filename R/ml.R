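#' Quartile contrast labels
#'
#' Converts a continuous target into a binary classification target by
#' quartile membership: `"1v4"` contrasts the first against the fourth
#' quartile (middle half excluded), `"123v4"` the first three against the
#' fourth, `"1v234"` the first against the last three. Quartiles are
#' assigned by average-tie fractional rank, so boundary ties resolve
#' deterministically. Label 1 is always the high side.
#'
#' @param y continuous values (>= 8 non-missing).
#' @param contrast one of `"1v4"`, `"123v4"`, `"1v234"`.
#' @return integer vector of labels 0/1 with `NA` for excluded samples.
#' @export
quartile_labels <- function(y, contrast = c("1v4", "123v4", "1v234")) {
  contrast <- match.arg(contrast)
  ok <- !is.na(y)
  if (sum(ok) < 8) stop("need at least 8 non-missing values")
  if (length(unique(y[ok])) < 2) stop("degenerate target: all values equal")
  pct <- rep(NA_real_, length(y))
  pct[ok] <- rank(y[ok], ties.method = "average") / sum(ok)
  q1 <- pct <= 0.25
  q4 <- pct > 0.75
  lab <- rep(NA_integer_, length(y))
  if (contrast == "1v4") {
    lab[q1] <- 0L; lab[q4] <- 1L
  } else if (contrast == "123v4") {
    lab[ok] <- ifelse(q4[ok], 1L, 0L)
  } else {
    lab[ok] <- ifelse(q1[ok], 0L, 1L)
  }
  lab
}

# rank-based AUC of scores for binary labels (probability that a random
# positive scores above a random negative; ties count half)
.auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Random forest model factory
#'
#' The documented default learner for [repeated_holdout_eval]: a
#' 1000-tree random forest with `sqrt(p)` candidate features per split.
#' Requires the `randomForest` package. Any other factory obeying the same
#' contract (a function of `(X, y, task)` returning a `function(X_new)`
#' of scores) can be injected instead.
#'
#' @param ntree number of trees (default 1000).
#' @return a model factory function.
#' @export
rf_factory <- function(ntree = 1000) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("the randomForest package is required for the default learner")
  function(X, y, task) {
    if (task == "classification") {
      fit <- randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                        ntree = ntree)
      function(Xn) stats::predict(fit, Xn, type = "prob")[, "1"]
    } else {
      fit <- randomForest::randomForest(X, y, ntree = ntree)
      function(Xn) as.numeric(stats::predict(fit, Xn))
    }
  }
}

#' Linear model factory
#'
#' A fast injectable learner: ridge-stabilised least squares on the
#' features (logistic-scale score for classification). Useful for
#' calibration checks of the evaluation harness where the learner itself
#' is not under study.
#'
#' @param lambda ridge penalty (default 1e-3).
#' @return a model factory function.
#' @export
lm_factory <- function(lambda = 1e-3) {
  function(X, y, task) {
    X <- as.matrix(X)
    mu <- colMeans(X); sdv <- pmax(apply(X, 2, stats::sd), 1e-12)
    Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    yy <- as.numeric(y)
    b <- solve(crossprod(Z) + diag(lambda, ncol(Z)),
               crossprod(Z, yy - mean(yy)))
    a <- mean(yy)
    function(Xn) {
      Zn <- sweep(sweep(as.matrix(Xn), 2, mu), 2, sdv, "/")
      as.numeric(a + Zn %*% b)
    }
  }
}

# group-aware stratified 80:20 split: groups (twin pairs; singletons are
# their own group) are the sampling unit, stratified by group-level label
# for classification so the test fold keeps a similar class ratio
.split_groups <- function(groups, labels, task, test_frac) {
  ug <- unique(groups)
  if (task == "classification") {
    glab <- vapply(ug, function(g) {
      round(mean(labels[groups == g]))
    }, numeric(1))
    # iterate strata in order of first-occurring group (not label value),
    # so the RNG draw sequence is invariant under label relabelling
    strata <- split(ug, glab)
    strata <- strata[order(vapply(strata, function(g) min(match(g, ug)),
                                  numeric(1)))]
    test_g <- unlist(lapply(strata, function(gl) {
      sample(gl, max(1, round(test_frac * length(gl))))
    }))
  } else {
    test_g <- sample(ug, max(1, round(test_frac * length(ug))))
  }
  which(groups %in% test_g)
}

#' Repeated-holdout association strength
#'
#' Quantifies how strongly a target is associated with the microbiome by
#' repeated stratified 80:20 train/test splits: the injected learner is
#' refit on each training fold and scored on the held-out fold, with AUC
#' for classification and Spearman correlation between truth and
#' prediction for regression. Members of one group (e.g. a twin pair)
#' are never split across folds. Deterministic given `seed`.
#'
#' @param X feature matrix (typically arcsine square-root transformed
#'   relative abundances), samples in rows.
#' @param y target: 0/1 labels (NA = excluded) for classification,
#'   numeric for regression.
#' @param task `"classification"` or `"regression"`.
#' @param model_factory a `function(X, y, task)` returning a
#'   `function(X_new)` of prediction scores; see [rf_factory],
#'   [lm_factory].
#' @param n_repeats number of repeated splits (default 100).
#' @param test_frac held-out fraction (default 0.2).
#' @param groups optional grouping key (twin pairs); default each sample
#'   alone.
#' @param seed master seed.
#' @return an `eval_result` list: `task`, `metric`, `per_repeat`, `mean`,
#'   `sd`, `n_repeats`, `n_redraws`.
#' @export
repeated_holdout_eval <- function(X, y, task = c("classification",
                                                 "regression"),
                                  model_factory = rf_factory(),
                                  n_repeats = 100, test_frac = 0.2,
                                  groups = NULL, seed = 1) {
  task <- match.arg(task)
  X <- as.matrix(X)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (is.null(groups)) groups <- seq_len(nrow(X)) else groups <- groups[keep]
  if (task == "classification" && !all(y %in% c(0, 1)))
    stop("classification labels must be 0/1 (NA = excluded)")
  set.seed(seed)
  vals <- numeric(n_repeats)
  redraws <- 0L
  for (r in seq_len(n_repeats)) {
    for (attempt in seq_len(11)) {
      test_idx <- .split_groups(groups, y, task, test_frac)
      train_idx <- setdiff(seq_along(y), test_idx)
      ok <- length(test_idx) > 0 && length(train_idx) > 0 &&
        (task == "regression" ||
           (length(unique(y[train_idx])) == 2 &&
              length(unique(y[test_idx])) == 2))
      if (ok) break
      if (attempt == 11) stop("could not draw a valid split in 10 redraws")
      redraws <- redraws + 1L
    }
    predict_fn <- model_factory(X[train_idx, , drop = FALSE], y[train_idx],
                                task)
    scores <- predict_fn(X[test_idx, , drop = FALSE])
    vals[r] <- if (task == "classification") .auc(scores, y[test_idx])
               else suppressWarnings(stats::cor(y[test_idx], scores,
                                                method = "spearman"))
  }
  structure(list(task = task,
                 metric = if (task == "classification") "auc" else "spearman",
                 per_repeat = vals, mean = mean(vals), sd = stats::sd(vals),
                 n_repeats = n_repeats, n_redraws = redraws),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result (%s): mean %s = %.3f (sd %.3f, %d repeats)\n",
              x$task, x$metric, x$mean, x$sd, x$n_repeats))
  invisible(x)
}
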