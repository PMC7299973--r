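# shared small survival problem
coxnet_problem <- function(n = 60, p = 5, seed = 21, beta1 = 0.7) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("v", seq_len(p))
    t <- rexp(n, 0.02 * exp(beta1 * X[, 1]))
    c_ <- rexp(n, 0.008)
    list(X = X, time = pmin(t, c_), event = as.integer(t <= c_))
  })
}

test_that("lambda_max is the smallest all-zero penalty (bisection oracle)", {
  pr <- coxnet_problem(p = 1)
  lam <- lambda_grid(pr$X, pr$time, pr$event, alpha = 1, n_lambda = 5)
  lmax <- attr(lam, "lambda_max")
  # bisection on the smallest lambda whose solution is all-zero
  is_zero <- function(l) {
    f <- coxnet_path(pr$X, pr$time, pr$event, alpha = 1, lambda = l)
    all(f$beta == 0)
  }
  expect_true(is_zero(lmax * 1.0000001))
  expect_false(is_zero(lmax * 0.98))
  lo <- lmax * 0.9; hi <- lmax * 1.1
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (is_zero(mid)) hi <- mid else lo <- mid
  }
  expect_equal(hi, lmax, tolerance = 1e-6)
  # halving alpha doubles lambda_max
  lam2 <- lambda_grid(pr$X, pr$time, pr$event, alpha = 0.5)
  expect_equal(attr(lam2, "lambda_max"), 2 * lmax, tolerance = 1e-12)
  expect_error(lambda_grid(pr$X, pr$time, pr$event, alpha = 0), "ridge")
})

test_that("solutions at or above lambda_max are all zero with clean KKT", {
  pr <- coxnet_problem(p = 8)
  lam <- lambda_grid(pr$X, pr$time, pr$event, alpha = 0.5, n_lambda = 30)
  lmax <- attr(lam, "lambda_max")
  f <- coxnet_path(pr$X, pr$time, pr$event, alpha = 0.5,
                   lambda = c(2 * lmax, 1.2 * lmax, lmax))
  expect_true(all(f$beta == 0))
  expect_true(all(f$kkt < 1e-8))
})

test_that("the lambda -> 0 limit reproduces the unpenalized Breslow fit", {
  pr <- coxnet_problem(n = 60, p = 5)
  lam <- lambda_grid(pr$X, pr$time, pr$event, alpha = 0.5, n_lambda = 60,
                     min_ratio = 1e-8)
  f <- coxnet_path(pr$X, pr$time, pr$event, alpha = 0.5, lambda = lam,
                   tol_cd = 1e-12, tol_irls = 1e-12)
  ref <- cox_fit(pr$X, pr$time, pr$event, ties = "breslow")
  expect_lt(max(abs(f$beta[, ncol(f$beta)] - ref$coef)), 1e-4)
})

test_that("every reported solution satisfies the KKT conditions", {
  pr <- coxnet_problem(n = 80, p = 12)
  for (alpha in c(1, 0.5)) {
    f <- coxnet_path(pr$X, pr$time, pr$event, alpha = alpha, n_lambda = 40,
                     tol_cd = 1e-11, tol_irls = 1e-11)
    expect_true(all(f$kkt < 1e-4 * max(f$lambda)))
    expect_true(all(f$monotone))
  }
})

test_that("warm-started path moves continuously in lambda", {
  pr <- coxnet_problem(n = 100, p = 10)
  f <- coxnet_path(pr$X, pr$time, pr$event, alpha = 0.5, n_lambda = 80)
  jumps <- apply(abs(diff(t(f$beta))), 1, max)
  expect_lt(max(jumps), 0.25)
})

test_that("path coefficients agree with glmnet along the whole grid", {
  skip_if_not_installed("glmnet")
  skip_if_not_installed("survival")
  pr <- coxnet_problem(n = 100, p = 10)
  lam <- lambda_grid(pr$X, pr$time, pr$event, alpha = 0.5, n_lambda = 30)
  f <- coxnet_path(pr$X, pr$time, pr$event, alpha = 0.5, lambda = lam,
                   tol_cd = 1e-11, tol_irls = 1e-11)
  g <- glmnet::glmnet(pr$X, survival::Surv(pr$time, pr$event),
                      family = "cox", alpha = 0.5, lambda = f$lambda,
                      standardize = TRUE, thresh = 1e-12)
  expect_equal(attr(lam, "lambda_max"), max(g$lambda), tolerance = 1e-8)
  expect_lt(max(abs(f$beta - as.matrix(g$beta))), 2e-4)
})

test_that("unpenalized columns stay in the model at every lambda", {
  pr <- coxnet_problem(n = 80, p = 6)
  f <- coxnet_path(pr$X, pr$time, pr$event, alpha = 1, n_lambda = 20,
                   penalty_free_idx = 1L)
  expect_true(all(f$beta[1, ] != 0))
  expect_true(all(f$beta[-1, 1] == 0))
})

test_that("cross-validation is deterministic and balanced", {
  pr <- coxnet_problem(n = 90, p = 10)
  a <- cv_coxnet(pr$X, pr$time, pr$event, alpha = 0.5, k = 3, fold_seed = 5)
  b <- cv_coxnet(pr$X, pr$time, pr$event, alpha = 0.5, k = 3, fold_seed = 5)
  expect_identical(a$folds, b$folds)
  expect_identical(a$cvm, b$cvm)
  expect_identical(a$nonzero_min, b$nonzero_min)
  expect_lte(diff(range(table(a$folds))), 1)
  expect_equal(a$lambda_min, a$lambda[which.min(a$cvm)])
})

test_that("cross-validation finds planted signal and stays quiet on noise", {
  # planted strong effect: selected at lambda_min in most replicates
  hits <- 0L
  for (r in 1:10) {
    coh <- make_planted_cohort(n = 300, p = 30, maf = 0.3,
                               log_hr = log(3), seed = 100 + r,
                               model = "additive")
    X <- snpstab:::impute_mean_dosage(coh$gm$codes)
    res <- cv_coxnet(X, coh$clinical$pfs_time, coh$clinical$pfs_event,
                     alpha = 0.5, k = 3, fold_seed = r, n_lambda = 40)
    hits <- hits + ("snp001" %in% res$nonzero_min)
  }
  expect_gte(hits, 9)
  # pure noise: nonzero set at lambda_min small in the typical replicate
  sizes <- integer(10)
  for (r in 1:10) {
    coh <- make_planted_cohort(n = 150, p = 50, maf = 0.3, log_hr = 0,
                               seed = 200 + r)
    X <- snpstab:::impute_mean_dosage(coh$gm$codes)
    res <- cv_coxnet(X, coh$clinical$pfs_time, coh$clinical$pfs_event,
                     alpha = 1, k = 3, fold_seed = r, n_lambda = 40)
    sizes[r] <- length(res$nonzero_min)
  }
  expect_lte(median(sizes), 2)
})
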