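# Independent oracle implementations used to cross-check the package's
# own code paths. These deliberately use different machinery (lm(),
# grid search, aov()) than the implementations they verify.

# partial Spearman by the definition: average-tie ranks, two lm()
# residualizations, then Pearson of the residuals
oracle_partial_spearman <- function(x, y, z = NULL) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (is.null(z) || NCOL(z) == 0) return(stats::cor(rx, ry))
  rz <- apply(as.matrix(z), 2, rank, ties.method = "average")
  ex <- stats::residuals(stats::lm(rx ~ rz))
  ey <- stats::residuals(stats::lm(ry ~ rz))
  stats::cor(ex, ey)
}

# Paule-Mandel tau2 by brute grid search of the moment criterion
oracle_pm_grid <- function(effects, variances, upper = 10, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  k <- length(effects)
  crit <- vapply(grid, function(t2) {
    w <- 1 / (variances + t2)
    yb <- sum(w * effects) / sum(w)
    sum(w * (effects - yb)^2) - (k - 1)
  }, numeric(1))
  if (crit[1] <= 0) return(0)
  i <- which(crit <= 0)[1]
  if (is.na(i)) return(upper)
  grid[i]
}

# ICC(2,1) from the aov() two-way ANOVA table
oracle_icc_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  target = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ target + rater, data = d))[[1]]
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# small abundance fixture: 4 samples x 3 SGBs
toy_table <- function() {
  abundance_table(matrix(c(0.25, 0.25, 0.25, 0.25,
                           0.5, 0.5, 0, 0,
                           1, 0, 0, 0,
                           0, 0, 0, 0), nrow = 4, byrow = TRUE,
                         dimnames = list(paste0("s", 1:4),
                                         paste0("SGB", 1:4))))
}

# write a tiny merged-profile TSV and return its path
toy_profile_tsv <- function() {
  path <- tempfile("profiles", fileext = ".tsv")
  writeLines(c(
    "clade_name\tNCBI_tax_id\tsampleA\tsampleB",
    "k__Bacteria\t2\t100.0\t100.0",
    "k__Bacteria|p__Firmicutes|g__Blautia\t572511\t60.0\t40.0",
    "k__Bacteria|p__Firmicutes|g__Blautia|s__B_glucerasea|t__SGB4816\t-1\t12.5\t40.0",
    "k__Bacteria|p__Firmicutes|s__R_torques|t__SGB4608_group\t-1\t87.5\t60.0"),
    path)
  path
}

# ranking fixture with known extreme structure
toy_ranking <- function(n = 10) {
  r <- (seq_len(n) - 0.5) / n
  structure(data.frame(sgb_id = sprintf("SGB%02d", seq_len(n)),
                       health_rank = r, diet_rank = rev(r),
                       n_cohorts_health = 2L, n_cohorts_diet = 2L,
                       stringsAsFactors = FALSE),
            class = c("ranking_table", "data.frame"))
}
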