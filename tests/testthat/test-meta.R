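test_that("fit_group_effect recovers a mean difference and flags collinearity", {
  est <- fit_group_effect(c(1, 2, 3, 4, 2, 3, 4, 5),
                          rep(c(0, 1), each = 4))
  expect_equal(est$beta, 1.0)
  expect_equal(est$n_control, 4)
  g <- rep(c(0, 1), each = 10)
  expect_error(fit_group_effect(rnorm(20), g, cbind(dup = g)),
               "collinear.*dup")
  expect_error(fit_group_effect(rnorm(7), c(0, 0, 0, 1, 1, 1, 1)),
               "at least 4")
})

test_that("adjusted beta recovers a simulated group effect", {
  set.seed(31)
  n <- 400
  g <- rbinom(n, 1, 0.5)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.5 * g + 0.8 * sex + rnorm(n)
  est <- fit_group_effect(y, g, cbind(sex = sex))
  expect_lt(abs(est$beta - 0.5), 0.15)
})

test_that("Cohen's d matches hand computation and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1.0)  # pooled SD = 1
  a <- rnorm(10); b <- rnorm(12)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "zero pooled SD")
})

test_that("beta_to_smd standardizes by the pooled outcome SD", {
  est <- fit_group_effect(c(1, 2, 3, 4, 2, 3, 4, 5), rep(c(0, 1), each = 4))
  est$beta <- 1; est$se <- 0.5; est$outcome_sd <- 2
  est <- beta_to_smd(est)
  expect_equal(est$smd, 0.5)
  expect_equal(est$smd_se, 0.25)
  est$beta <- 0
  expect_equal(beta_to_smd(est)$smd, 0)
  est$outcome_sd <- 0
  expect_error(beta_to_smd(est), "positive")
})

test_that("smd is consistent with raw Cohen's d on covariate-free groups", {
  set.seed(32)
  n <- 500
  g <- rep(c(0, 1), each = n / 2)
  y <- 0.4 * g + rnorm(n)
  est <- beta_to_smd(fit_group_effect(y, g))
  expect_lt(abs(est$smd - cohens_d(y[g == 1], y[g == 0])), 0.1)
})

test_that("Paule-Mandel handles homogeneous, symmetric and degenerate cases", {
  hom <- paule_mandel(c(0.5, 0.5), c(0.1, 0.1))
  expect_equal(hom$tau2, 0)
  expect_equal(hom$pooled, 0.5)
  sym <- paule_mandel(c(0, 1), c(0.01, 0.01))
  expect_gt(sym$tau2, 0)
  expect_equal(sym$pooled, 0.5, tolerance = 1e-8)
  expect_warning(one <- paule_mandel(0.3, 0.04), "single study")
  expect_equal(one$pooled, 0.3)
  expect_equal(one$tau2, 0)
  expect_error(paule_mandel(c(0, 1), c(0, 0.1)), "positive")
})

test_that("Paule-Mandel matches the grid oracle and metafor on fixtures", {
  set.seed(33)
  skip_if_not_installed("metafor")
  for (i in 1:10) {
    k <- sample(3:8, 1)
    eff <- rnorm(k, 0.3, 0.5)
    v <- runif(k, 0.01, 0.2)
    pm <- paule_mandel(eff, v)
    expect_lt(abs(pm$tau2 - oracle_pm_grid(eff, v)), 2e-4)
    mf <- metafor::rma(yi = eff, vi = v, method = "PM")
    expect_lt(abs(pm$tau2 - mf$tau2), 1e-4)
    expect_lt(abs(pm$pooled - as.numeric(mf$beta)), 1e-4)
  }
})

test_that("pooled estimates shift with a common additive constant", {
  set.seed(34)
  eff <- rnorm(5); v <- runif(5, 0.05, 0.2)
  p0 <- paule_mandel(eff, v)
  p1 <- paule_mandel(eff + 2, v)
  expect_equal(p1$pooled, p0$pooled + 2, tolerance = 1e-7)
  expect_equal(p1$tau2, p0$tau2, tolerance = 1e-7)
  expect_true(p0$ci95[1] <= p0$pooled && p0$pooled <= p0$ci95[2])
  expect_equal(sum(p0$weights), 1)
})

test_that("equal variances and zero heterogeneity give the arithmetic mean", {
  eff <- c(0.2, 0.21, 0.19, 0.2)
  pm <- paule_mandel(eff, rep(0.5, 4))
  expect_equal(pm$tau2, 0)
  expect_equal(pm$pooled, mean(eff))
})

test_that("shared-control covariance follows the multi-arm approximation", {
  mk_est <- function(smd, se, n0, n1) {
    structure(list(beta = NA, se = NA, n_control = n0, n_case = n1,
                   outcome_sd = 1, smd = smd, smd_se = se, d = NA,
                   covariates = character()), class = "effect_estimate")
  }
  # SEs consistent with the group sizes (var ~ 1/n0 + 1/n1)
  ests <- list(mk_est(0, 0.142, 100, 100), mk_est(0, 0.136, 100, 120))
  V0 <- shared_control_covariance(ests)
  expect_equal(V0, diag(c(0.142^2, 0.136^2)))   # no overlap -> diagonal
  V <- shared_control_covariance(ests, list("1:2" = 100))
  expect_equal(V[1, 2], 0.01)                   # 1/n_c with zero effects
  ests2 <- list(mk_est(0.5, 0.15, 100, 100), mk_est(0.3, 0.14, 100, 120))
  V2 <- shared_control_covariance(ests2, list("1:2" = 80))
  expect_equal(V2[1, 2], 1 / 80 + 0.5 * 0.3 / (2 * (200 + 220)))
  expect_error(shared_control_covariance(ests, list("1:2" = 150)),
               "exceeds")
})

test_that("shared-control covariance is positive definite on random fixtures", {
  set.seed(35)
  mk_est <- function(smd, se, n0, n1) {
    structure(list(beta = NA, se = NA, n_control = n0, n_case = n1,
                   outcome_sd = 1, smd = smd, smd_se = se, d = NA,
                   covariates = character()), class = "effect_estimate")
  }
  for (i in 1:100) {
    k <- sample(3:6, 1)
    ests <- lapply(seq_len(k), function(j) {
      n0 <- sample(50:200, 1); n1 <- sample(50:200, 1)
      d <- rnorm(1, 0, 0.5)
      # size-consistent SMD standard error (Hedges approximation)
      mk_est(d, sqrt(1 / n0 + 1 / n1 + d^2 / (2 * (n0 + n1))), n0, n1)
    })
    # the shared pair reuses one whole control arm, as when one study's
    # controls serve two disease comparisons
    pair <- sample(k, 2)
    n_c <- ests[[pair[1]]]$n_control
    ests[[pair[2]]]$n_control <- n_c
    ests[[pair[2]]]$smd_se <- sqrt(1 / n_c + 1 / ests[[pair[2]]]$n_case +
      ests[[pair[2]]]$smd^2 / (2 * (n_c + ests[[pair[2]]]$n_case)))
    ov <- list()
    ov[[paste(pair, collapse = ":")]] <- n_c
    V <- shared_control_covariance(ests, ov)
    expect_true(all(eigen(V, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("GLS pooling reduces to inverse-variance weighting for diagonal covariance", {
  set.seed(36)
  y <- rnorm(4); v <- runif(4, 0.02, 0.1)
  got <- pool_shared_controls(y, diag(v))
  expect_equal(got$pooled, sum(y / v) / sum(1 / v), tolerance = 1e-12)
  expect_equal(got$se, 1 / sqrt(sum(1 / v)), tolerance = 1e-12)
})

test_that("GLS pooling matches a direct matrix-algebra oracle with overlap", {
  y <- c(0.4, 0.3, 0.6)
  V <- diag(c(0.04, 0.05, 0.03))
  V[1, 2] <- V[2, 1] <- 0.015
  Vi <- solve(V)
  one <- rep(1, 3)
  expect_equal(pool_shared_controls(y, V)$pooled,
               as.numeric(one %*% Vi %*% y) / as.numeric(one %*% Vi %*% one),
               tolerance = 1e-10)
  # two perfectly correlated identical studies: no information doubling
  V2 <- matrix(0.04, 2, 2) + diag(1e-12, 2)
  got <- pool_shared_controls(c(0.5, 0.5), V2)
  expect_equal(got$pooled, 0.5, tolerance = 1e-6)
  expect_equal(got$se, 0.2, tolerance = 1e-3)
})

test_that("binomial sign test matches exact tail doubling", {
  expect_equal(binomial_sign_test(5, 5), 0.0625)   # 2 * (1/32)
  expect_equal(binomial_sign_test(4, 8), 1.0)      # capped at the mode
  expect_equal(binomial_sign_test(21, 25, "greater"),
               pbinom(20, 25, 0.5, lower.tail = FALSE))
  expect_equal(binomial_sign_test(3, 10), binomial_sign_test(7, 10))
  expect_error(binomial_sign_test(5, 4), "0 <= k <= n")
})

test_that("mixed country model matches OLS under zero dataset effects", {
  set.seed(37)
  n_ds <- 6; n_per <- 40
  dataset <- rep(sprintf("d%d", 1:n_ds), each = n_per)
  country <- rep(rep(c("A", "B"), each = n_per), 3)
  depth <- runif(n_ds * n_per, 1, 10)
  y <- 0.5 * (country == "B") + 0.02 * depth + rnorm(n_ds * n_per, 0, 0.5)
  mm <- mixed_country_effect(y, country, dataset, depth)
  ols <- summary(lm(y ~ country + depth))$coefficients[2, ]
  expect_equal(mm$method, "lmm")
  expect_lt(abs(mm$beta - ols[1]), 2 * ols[2])
})

test_that("mixed model shrinks dataset-confounded bias relative to OLS", {
  # one large dataset per country dominates the OLS estimate; the random
  # intercept re-weights datasets towards equality, averaging the
  # dataset-level intercepts instead of following the dominant one
  set.seed(38)
  wins <- 0; reps <- 20
  for (r in seq_len(reps)) {
    sizes <- c(200, 15, 15, 200, 15, 15)
    dataset <- rep(sprintf("d%d", 1:6), times = sizes)
    country <- rep(c("A", "A", "A", "B", "B", "B"), times = sizes)
    ds_eff <- rep(rnorm(6, 0, 1), times = sizes)
    depth <- runif(sum(sizes), 1, 10)
    y <- ds_eff + rnorm(sum(sizes), 0, 0.3)   # true country effect is 0
    mm <- suppressMessages(mixed_country_effect(y, country, dataset, depth))
    ols <- unname(coef(lm(y ~ country + depth))[2])
    if (abs(mm$beta) <= abs(ols)) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.6)
})

test_that("single dataset per country falls back to depth-adjusted OLS", {
  set.seed(39)
  n <- 60
  dataset <- rep(c("d1", "d2"), each = n / 2)
  country <- rep(c("A", "B"), each = n / 2)
  depth <- runif(n, 1, 10)
  y <- rnorm(n)
  expect_message(mm <- mixed_country_effect(y, country, dataset, depth),
                 "falling back")
  expect_equal(mm$method, "ols")
})
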