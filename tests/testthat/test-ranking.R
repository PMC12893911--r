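test_that("partial Spearman recovers exact monotone relationships", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 0.2)
  expect_equal(partial_spearman(x, x)$rho, 1.0)
  expect_equal(partial_spearman(x, -exp(x))$rho, -1.0)  # monotone invariance
  expect_equal(partial_spearman(x, x^3)$rho, 1.0)
})

test_that("partial Spearman equals plain Spearman with no covariates", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    expect_equal(partial_spearman(x, y)$rho,
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("partial Spearman matches the rank-residual oracle with covariates", {
  set.seed(12)
  n <- 12
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.4 * z + rnorm(n)
  got <- partial_spearman(x, y, cbind(z))
  expect_equal(got$rho, oracle_partial_spearman(x, y, z), tolerance = 1e-10)
  expect_equal(got$n, n)
  # p from the t distribution with n - 2 - k df
  tt <- got$rho * sqrt((n - 3) / (1 - got$rho^2))
  expect_equal(got$p, 2 * pt(-abs(tt), n - 3))
})

test_that("partial Spearman signals degenerate inputs instead of silently returning", {
  x <- rep(1, 20)
  y <- rnorm(20)
  expect_error(partial_spearman(x, y), "constant")
  expect_error(partial_spearman(rnorm(5), rnorm(5)), "insufficient")
})

test_that("independent covariates barely change rho at large n", {
  set.seed(13)
  n <- 2000
  x <- rnorm(n); y <- 0.4 * x + rnorm(n); z <- rnorm(n)
  plain <- partial_spearman(x, y)$rho
  adj <- partial_spearman(x, y, cbind(z))$rho
  expect_lt(abs(plain - adj), 0.05)
})

test_that("correlate_all returns one cell per pair and agrees with the scalar path", {
  set.seed(14)
  n <- 60
  m <- matrix(rexp(n * 5) / 100, n, 5,
              dimnames = list(sprintf("s%02d", 1:n), paste0("SGB", 1:5)))
  tab <- abundance_table(m)
  mk <- matrix(rnorm(n * 3), n, 3,
               dimnames = list(rownames(m), c("m1", "m2", "m3")))
  cov <- matrix(rnorm(n * 2), n, 2,
                dimnames = list(rownames(m), c("age", "bmi")))
  frame <- correlate_all(tab, mk, cov, min_n = 30)
  expect_equal(nrow(frame), 15)
  for (i in c(1, 7, 15)) {
    ref <- partial_spearman(m[, frame$sgb_id[i]], mk[, frame$marker[i]], cov)
    expect_equal(frame$rho[i], ref$rho, tolerance = 1e-12)
    expect_equal(frame$p[i], ref$p, tolerance = 1e-12)
  }
})

test_that("correlate_all flags all-missing markers and thin cells as unranked", {
  set.seed(15)
  n <- 40
  m <- matrix(runif(n * 2) / 50, n, 2,
              dimnames = list(sprintf("s%02d", 1:n), c("SGBa", "SGBb")))
  mk <- cbind(good = rnorm(n), empty = rep(NA_real_, n),
              thin = c(rnorm(10), rep(NA, n - 10)))
  rownames(mk) <- rownames(m)
  frame <- correlate_all(abundance_table(m), mk, min_n = 30)
  expect_true(all(is.na(frame$rho[frame$marker %in% c("empty", "thin")])))
  expect_true(all(!is.na(frame$rho[frame$marker == "good"])))
  expect_error(correlate_all(abundance_table(m), mk[0, , drop = FALSE]),
               "overlap")
})

test_that("marker percentiles orient by direction and average ties", {
  panel <- marker_panel(c("up", "down"), "fasting", c(1, -1))
  frame <- data.frame(
    sgb_id = rep(c("A", "B", "C"), 2),
    marker = rep(c("up", "down"), each = 3),
    rho = c(0.9, 0.1, -0.4,      # oriented as-is for direction +1
            -0.9, -0.1, 0.4),    # direction -1 flips to the same order
    p = NA, n = 50)
  pct <- marker_percentiles(frame, panel)
  expect_equal(unname(pct[, "up"]), c(1, 2, 3) / 3)
  expect_equal(unname(pct[, "down"]), c(1, 2, 3) / 3)
  # tie -> average of positional percentiles
  frame2 <- frame[1:3, ]
  frame2$rho <- c(0.5, 0.5, -0.1)
  pct2 <- marker_percentiles(frame2, panel)
  expect_equal(unname(pct2[, "up"]), c(1.5 / 3, 1.5 / 3, 1))
  expect_error(marker_percentiles(frame2, marker_panel("other", "fasting", 1)),
               "missing")
})

test_that("flipping all oriented scores reverses the percentile order", {
  set.seed(16)
  panel <- marker_panel("m", "fasting", 1)
  n <- 9
  rho <- rnorm(n)
  fr <- data.frame(sgb_id = paste0("S", 1:n), marker = "m", rho = rho,
                   p = NA, n = 50)
  fr_flip <- fr; fr_flip$rho <- -rho
  p1 <- marker_percentiles(fr, panel)[, 1]
  p2 <- marker_percentiles(fr_flip, panel)[, 1]
  expect_equal(unname(p2), unname((n + 1) / n - p1))
  # distinct scores -> percentile multiset is {1/n, ..., 1}
  expect_equal(sort(unname(p1)), (1:n) / n)
})

test_that("build_ranking averages categories then cohorts and enforces retention", {
  panel <- marker_panel(c("p1", "f1", "f2", "d1"),
                        c("personal", "fasting", "fasting", "dietary"),
                        c(1, 1, 1, 1))
  # cohort A: SGB X in all markers; cohort B: X again; C only in cohort A
  pctA <- matrix(c(0.2, 0.2, 0.2, 0.3,
                   0.6, 0.8, 1.0, 0.5),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("X", "C"), c("p1", "f1", "f2", "d1")))
  pctB <- matrix(c(0.4, 0.3, 0.5, 0.7), nrow = 1,
                 dimnames = list("X", c("p1", "f1", "f2", "d1")))
  rk <- build_ranking(list(A = pctA, B = pctB), panel, min_cohorts = 2)
  # cohort A health value for X: mean(personal 0.2, fasting mean 0.2) = 0.2
  # cohort B: mean(0.4, mean(0.3, 0.5)) = 0.4; final = 0.3
  x <- rk[rk$sgb_id == "X", ]
  expect_equal(x$health_rank, 0.3)
  expect_equal(x$diet_rank, 0.5)
  expect_equal(x$n_cohorts_health, 2L)
  # C ranked in one cohort only -> no final rank under min_cohorts = 2
  expect_true(is.na(rk$health_rank[rk$sgb_id == "C"]))
  # identical percentiles in all cohorts -> final equals the common value
  rk1 <- build_ranking(list(A = pctA, B = pctA), panel, min_cohorts = 2)
  expect_equal(rk1$health_rank[rk1$sgb_id == "X"], 0.2)
})

test_that("missing cohort-category combinations are skipped in averaging", {
  panel <- marker_panel(c("p1", "f1", "d1"),
                        c("personal", "fasting", "dietary"), 1)
  # cohort B has no dietary marker at all (e.g. no FFQ collected)
  pctA <- matrix(c(0.2, 0.4, 0.6), 1,
                 dimnames = list("X", c("p1", "f1", "d1")))
  pctB <- matrix(c(0.4, 0.6), 1, dimnames = list("X", c("p1", "f1")))
  rk <- build_ranking(list(A = pctA, B = pctB), panel, min_cohorts = 2)
  expect_equal(rk$health_rank, mean(c(mean(c(0.2, 0.4)), mean(c(0.4, 0.6)))))
  expect_true(is.na(rk$diet_rank))  # dietary ranked in one cohort only
  expect_equal(rk$n_cohorts_diet, 1L)
})

test_that("ICC is 1 for identical columns and matches the ANOVA oracle", {
  m <- matrix(runif(18), 6, 3)
  expect_equal(icc_agreement(cbind(m[, 1], m[, 1], m[, 1]))$icc, 1.0)
  fix <- matrix(c(0.10, 0.15, 0.20,
                  0.30, 0.25, 0.40,
                  0.50, 0.55, 0.45,
                  0.70, 0.60, 0.75,
                  0.85, 0.90, 0.80,
                  0.95, 0.98, 0.90), 6, 3, byrow = TRUE)
  expect_equal(icc_agreement(fix)$icc, oracle_icc_anova(fix),
               tolerance = 1e-12)
  expect_error(icc_agreement(fix[, 1, drop = FALSE]), "two columns")
  expect_error(icc_agreement(fix[1:2, ]), "insufficient")
})

test_that("ICC of independent random columns is near zero", {
  set.seed(17)
  m <- matrix(rnorm(600), 200, 3)
  expect_lt(abs(icc_agreement(m)$icc), 0.15)
})

test_that("rank concordance handles identity, reversal and disjoint ids", {
  r <- setNames((1:20) / 20, paste0("S", 1:20))
  expect_equal(rank_concordance(r, r)$rho, 1.0)
  rev_r <- setNames(rev(unname(r)), names(r))
  expect_equal(rank_concordance(r, rev_r)$rho, -1.0)
  other <- setNames(r, paste0("T", 1:20))
  expect_error(rank_concordance(r, other), "insufficient")
})

test_that("covariate adjustment removes BMI-confounded spurious rankings", {
  # half of the null species load on BMI, as do all markers; without
  # adjustment they crowd the extremes and displace the planted species
  recovery <- function(covars, r) {
    truth <- planted_truth(sgb_universe(60), 8, 8, effect_size = 0.4)
    sim <- generate_multi_cohort(
      list(cohort_sim_config("C1", 300, 60, bmi_confounding = 1.2,
                             seed = 4000 + r),
           cohort_sim_config("C2", 300, 60, bmi_confounding = 1.2,
                             seed = 4100 + r)), truth)
    meta <- do.call(rbind, lapply(sim$cohorts, `[[`, "meta"))
    rk <- rank_species(lapply(sim$cohorts, `[[`, "table"),
                       lapply(sim$cohorts, `[[`, "markers"),
                       meta, sim$panel, covariates = covars)
    hr <- setNames(rk$health_rank, rk$sgb_id)
    q <- quantile(hr, c(0.25, 0.75), na.rm = TRUE)
    fav <- truth$sgb_id[truth$effect_direction == 1]
    unf <- truth$sgb_id[truth$effect_direction == -1]
    sum(hr[fav] <= q[1], na.rm = TRUE) + sum(hr[unf] >= q[2], na.rm = TRUE)
  }
  adjusted <- sum(vapply(1:20, function(r)
    recovery(c("sex", "age", "bmi"), r), numeric(1)))
  unadjusted <- sum(vapply(1:20, function(r)
    recovery(character(0), r), numeric(1)))
  expect_gt(adjusted, unadjusted)
})
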