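test_that("Kaplan-Meier estimator matches hand computation and the ECDF", {
  # hand-computed product-limit: times 1,2,3 with events 1,0,1
  k <- km(c(1, 2, 3), c(1, 0, 1))
  expect_equal(k$table$surv, c(2 / 3, 2 / 3, 0))
  # no censoring: curve equals 1 - ECDF at every event time
  set.seed(1)
  t <- rexp(200, 0.1)
  k2 <- km(t, rep(1, 200))
  expect_equal(k2$table$surv, 1 - ecdf(t)(k2$table$time))
  # single patient with an event at 5
  k3 <- km(5, 1)
  expect_equal(k3$table$surv, 0)
  expect_equal(km_surv_at(k3, c(4.9, 5)), c(1, 0))
  expect_equal(k3$median, 5)
  expect_error(km(numeric(0), numeric(0)), "no usable")
})

test_that("log-rank test matches symmetry, separation and df expectations", {
  t <- c(1, 3, 5, 7, 9)
  e <- c(1, 0, 1, 1, 0)
  dup <- logrank(c(t, t), c(e, e), rep(1:2, each = 5))
  expect_equal(dup$statistic, 0, tolerance = 1e-12)
  expect_equal(dup$p, 1)
  # completely separated event times
  sep <- logrank(c(1:20, 101:120), rep(1, 40), rep(1:2, each = 20))
  expect_lt(sep$p, 1e-4)
  # three groups give 2 df
  set.seed(2)
  lr3 <- logrank(rexp(60), rbinom(60, 1, 0.8), rep(1:3, each = 20))
  expect_equal(lr3$df, 2)
  expect_error(logrank(t, e, rep(1, 5)), "2 groups")
})

test_that("log-rank agrees with survdiff and with the Cox score test", {
  skip_if_not_installed("survival")
  set.seed(3)
  n <- 120
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.02 * exp(0.4 * g))
  c_ <- rexp(n, 0.01)
  time <- pmin(t, c_)
  ev <- as.integer(t <= c_)
  mine <- logrank(time, ev, g)
  ref <- survival::survdiff(survival::Surv(time, ev) ~ g)
  expect_equal(mine$statistic, unname(ref$chisq), tolerance = 1e-10)
  # equals the score test of the Breslow Cox fit on the group indicator
  # (no tied event times here)
  sc <- survival::coxph(survival::Surv(time, ev) ~ g, ties = "breslow")
  expect_equal(mine$statistic, unname(sc$score), tolerance = 1e-6)
})

test_that("cox_fit maximizes the partial likelihood (grid-search oracle)", {
  # 8 patients, one covariate, no ties: grid search over the explicit
  # partial likelihood
  x <- c(0.5, -1.2, 0.3, 1.8, -0.7, 0.1, -0.4, 1.1)
  time <- c(3, 6, 8, 11, 15, 21, 24, 30)
  ev <- c(1, 0, 1, 1, 0, 1, 1, 0)
  pl <- function(b) {
    eta <- b * x
    sum(vapply(which(ev == 1), function(i) {
      eta[i] - log(sum(exp(eta[time >= time[i]])))
    }, numeric(1)))
  }
  grid <- seq(-3, 3, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, pl, numeric(1)))]
  fit <- cox_fit(matrix(x, ncol = 1), time, ev)
  expect_lt(abs(unname(fit$coef) - b_grid), 1e-4 + 1e-6)
  expect_lt(fit$score_max, 1e-8)
  expect_true(fit$converged)
})

test_that("cox_fit is zero under group-swap symmetry and rejects bad designs", {
  # duplicated data with swapped groups is symmetric under relabelling
  t <- c(2, 4, 6, 8)
  e <- c(1, 1, 0, 1)
  X <- matrix(c(0, 0, 1, 1, 1, 1, 0, 0), ncol = 1)
  fit <- cox_fit(X, c(t, t), c(e, e))
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)
  expect_equal(unname(fit$hr), 1, tolerance = 1e-8)
  # collinear design
  set.seed(4)
  Z <- matrix(rnorm(40), ncol = 2)
  expect_error(cox_fit(cbind(Z, Z[, 1]), rexp(20), rbinom(20, 1, 0.9)),
               "collinear")
  expect_error(cox_fit(cbind(Z[, 1], 1), rexp(20), rbinom(20, 1, 0.9)),
               "constant")
  expect_error(cox_fit(Z, rexp(20), rep(0, 20)), "no events")
})

test_that("Efron and Breslow coincide without ties and match coxph with ties", {
  skip_if_not_installed("survival")
  set.seed(5)
  n <- 80
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  t <- rexp(n, 0.05 * exp(0.3 * X[, 1]))
  ev <- rbinom(n, 1, 0.8)
  fe <- cox_fit(X, t, ev, ties = "efron")
  fb <- cox_fit(X, t, ev, ties = "breslow")
  expect_equal(fe$coef, fb$coef, tolerance = 1e-12)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-12)
  # heavy ties: match coxph under both conventions
  tt <- round(t / 20) * 20 + 1
  for (ties in c("efron", "breslow")) {
    mine <- cox_fit(X, tt, ev, ties = ties)
    ref <- survival::coxph(survival::Surv(tt, ev) ~ X, ties = ties)
    expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
  }
})

test_that("stratified fits and survival prediction match the survival package", {
  skip_if_not_installed("survival")
  set.seed(6)
  n <- 150
  X <- cbind(x = rnorm(n))
  str <- factor(rep(c("A", "B", "C"), each = 50))
  base <- c(A = 0.02, B = 0.05, C = 0.01)[as.character(str)]
  t <- rexp(n, base * exp(0.5 * X[, 1]))
  ev <- rbinom(n, 1, 0.85)
  mine <- cox_fit(X, t, ev, strata = str)
  ref <- survival::coxph(survival::Surv(t, ev) ~ X + strata(str),
                         ties = "efron")
  expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-7)
  # Breslow-basis survival prediction against survfit
  fit2 <- cox_fit(X, t, ev, ties = "breslow")
  ref2 <- survival::coxph(survival::Surv(t, ev) ~ X, ties = "breslow")
  newd <- data.frame(X = c(-1, 0, 1.5))
  times <- c(10, 30, 60)
  sf <- survival::survfit(ref2, newdata = newd, ctype = 1, stype = 2)
  refs <- t(summary(sf, times = times)$surv)
  mines <- cox_predict_survival(fit2, matrix(newd$X, ncol = 1), times)
  expect_equal(unname(mines), unname(refs), tolerance = 1e-6)
})

test_that("genotype association reports HRs, Wald tests and group sizes", {
  coh <- make_planted_cohort(n = 600, log_hr = log(2), seed = 9)
  rec <- genotype_association(coh$gm, "snp001", "dominant", coh$clinical,
                              covariates = c("sex", "age"),
                              endpoint = "pfs")
  expect_false(rec$inestimable)
  expect_equal(rec$wald_df, 1)
  expect_gt(rec$hr, 1.4)
  expect_lt(rec$hr, 3)
  expect_equal(rec$n_used,
               rec$n_hom_major + rec$n_het + rec$n_hom_minor)
  cod <- genotype_association(coh$gm, "snp002", "codominant", coh$clinical,
                              endpoint = "pfs")
  expect_equal(nrow(cod), 2)
  expect_equal(unique(cod$wald_df), 2)
  # codominant on a SNP with no minor homozygotes is inestimable
  gm <- coh$gm
  gm$codes[gm$codes[, "snp003"] == 2L, "snp003"] <- 1L
  bad <- genotype_association(gm, "snp003", "codominant", coh$clinical,
                              endpoint = "pfs")
  expect_true(all(bad$inestimable))
  expect_match(bad$note[1], "empty genotype group")
})
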