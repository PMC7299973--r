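# Shared preprocessing: sort by time, build unique-time indices, and
# standardize predictors to zero mean / unit population variance.
coxnet_prep <- function(X, time, event) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X) || anyNA(time) || anyNA(event)) {
    stop("penalized solver requires complete data (impute upstream)",
         call. = FALSE)
  }
  if (sum(event) < 1) stop("no events in the data", call. = FALSE)
  ord <- order(time)
  Xs <- X[ord, , drop = FALSE]
  time <- time[ord]; event <- as.integer(event[ord])
  uid <- cumsum(!duplicated(time))
  n <- nrow(Xs)
  ctr <- colMeans(Xs)
  sd_pop <- sqrt(colMeans(Xs^2) - ctr^2)
  scale_ <- ifelse(sd_pop > 0, sd_pop, 1)
  Z <- sweep(sweep(Xs, 2, ctr), 2, scale_, "/")
  list(Z = Z, time = time, event = event, uid = as.integer(uid),
       K = max(uid), n = n, p = ncol(Xs), center = ctr, scale = scale_,
       sd_zero = sd_pop == 0, order = ord, names = colnames(X))
}

# Breslow log partial likelihood at a standardized-scale linear predictor
coxnet_loglik <- function(prep, beta_std) {
  eta <- drop(prep$Z %*% beta_std)
  cox_breslow_loglik_cpp(eta, prep$event, prep$uid, prep$K)
}

#' Regularization-path lambda sequence for the penalized Cox model
#'
#' `lambda_max` is the smallest penalty at which the all-zero solution
#' satisfies the Karush-Kuhn-Tucker conditions: the sup-norm of the
#' partial-likelihood gradient (per observation, standardized predictors)
#' divided by `alpha`.  The sequence is log-spaced from `lambda_max` down
#' to `lambda_max * min_ratio`.
#'
#' @param X predictor matrix (standardized internally).
#' @param time,event survival outcome.
#' @param alpha elastic-net mixing in `(0, 1]` (1 = LASSO).
#' @param n_lambda sequence length.
#' @param min_ratio smallest lambda as a fraction of `lambda_max`;
#'   defaults to 0.05 when `P > N`, else 0.01.
#' @return Decreasing numeric vector of length `n_lambda` with attribute
#'   `lambda_max`.
#' @export
lambda_grid <- function(X, time, event, alpha = 1, n_lambda = 100,
                        min_ratio = NULL) {
  if (alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]; pure ridge has no finite lambda_max",
         call. = FALSE)
  }
  prep <- coxnet_prep(X, time, event)
  if (is.null(min_ratio)) min_ratio <- if (prep$p > prep$n) 0.05 else 0.01
  g0 <- cox_score_eta(prep, numeric(prep$p))
  lmax <- max(abs(crossprod(prep$Z, g0)) / prep$n) / alpha
  out <- exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
  attr(out, "lambda_max") <- lmax
  out
}

# gradient of the Breslow log partial likelihood wrt eta, standardized data
cox_score_eta <- function(prep, beta_std) {
  eta <- drop(prep$Z %*% beta_std)
  ev <- prep$event; uid <- prep$uid; K <- prep$K
  w <- exp(eta - mean(eta))
  agg <- function(v) {
    out <- numeric(K); s <- rowsum(v, uid)
    out[as.integer(rownames(s))] <- s; out
  }
  S0 <- rev(cumsum(rev(agg(w))))
  d <- agg(as.numeric(ev))
  C1 <- cumsum(ifelse(d > 0, d / S0, 0))
  ev - w * C1[uid]
}

#' Elastic-net Cox regularization path
#'
#' Solves, for each penalty value, the elastic-net penalized Breslow
#' partial likelihood `-loglik/n + lambda * (alpha * ||b||_1 +
#' (1 - alpha)/2 * ||b||_2^2)` by cyclic coordinate descent on the IRLS
#' quadratic approximation, warm-starting along the decreasing lambda
#' sequence.  Predictors are standardized internally (population
#' variance); coefficients are returned on the original scale.
#'
#' @param X complete predictor matrix.
#' @param time,event survival outcome.
#' @param alpha elastic-net mixing in `(0, 1]`.
#' @param lambda decreasing penalty sequence; defaults to
#'   [lambda_grid()].
#' @param penalty_free_idx column indices left unpenalized (e.g. clinical
#'   covariates forced into the model).
#' @param n_lambda,min_ratio passed to [lambda_grid()] when `lambda` is
#'   `NULL`.
#' @param tol_cd coordinate-descent convergence tolerance (weighted
#'   squared coefficient change, standardized scale).
#' @param tol_irls outer-loop convergence tolerance on the weighted
#'   squared coefficient change across one IRLS step.
#' @param dfmax stop the path once a solution holds more than this many
#'   nonzero coefficients (the truncating solution is kept); default
#'   no bound.
#' @return A `coxnet_path`: list with `beta` (P x n_lambda, original
#'   scale), `lambda`, `alpha`, `nonzero` counts, `loglik`, `kkt` max
#'   violation per lambda, `iter`, and a `monotone` flag per lambda
#'   recording that the penalized objective never increased across IRLS
#'   steps.
#' @export
coxnet_path <- function(X, time, event, alpha = 1, lambda = NULL,
                        penalty_free_idx = integer(0), n_lambda = 100,
                        min_ratio = NULL, tol_cd = 1e-8, tol_irls = 1e-8,
                        dfmax = NULL) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  prep <- coxnet_prep(X, time, event)
  if (is.null(lambda)) {
    lambda <- lambda_grid(X, time, event, alpha, n_lambda, min_ratio)
  }
  if (is.null(dfmax)) dfmax <- prep$p + 1L
  pf <- rep(1, prep$p)
  pf[penalty_free_idx] <- 0
  res <- coxnet_path_cpp(prep$Z, prep$event, prep$uid, prep$K, alpha,
                         as.numeric(lambda), pf, tol_cd, tol_irls,
                         50L, 10000L, as.integer(dfmax))
  keep <- seq_len(res$n_computed)
  beta_std <- res$beta[, keep, drop = FALSE]
  beta <- beta_std / prep$scale
  rownames(beta) <- prep$names
  structure(list(
    beta = beta, beta_std = beta_std, lambda = as.numeric(lambda)[keep],
    alpha = alpha, nonzero = colSums(beta_std != 0),
    loglik = res$loglik[keep], kkt = res$kkt[keep], iter = res$iter[keep],
    monotone = as.logical(res$monotone)[keep],
    penalty_free_idx = penalty_free_idx,
    center = prep$center, scale = prep$scale
  ), class = "coxnet_path")
}

#' @export
print.coxnet_path <- function(x, ...) {
  cat(sprintf("coxnet path: alpha = %.2f, %d lambdas, nonzero %d..%d\n",
              x$alpha, length(x$lambda), min(x$nonzero), max(x$nonzero)))
  invisible(x)
}

#' Cross-validated elastic-net Cox regression
#'
#' K-fold cross-validation of [coxnet_path()] with the cross-validated
#' partial likelihood of Verweij and Van Houwelingen: each fold
#' contributes `-2 * (loglik(full data at fold-trained beta) -
#' loglik(training data at fold-trained beta))`.  `lambda_min` minimizes
#' the mean deviance over folds; the reported nonzero set is taken from
#' the full-data path at `lambda_min`.
#'
#' @param X,time,event,alpha,lambda,penalty_free_idx,n_lambda,min_ratio
#'   as in [coxnet_path()].
#' @param k number of folds (>= 2), assigned by seeded permutation with
#'   sizes differing by at most one.
#' @param fold_seed integer seed for the fold assignment.
#' @param max_redraw fold redraws allowed when a training set has no
#'   events.
#' @param tol_cd,tol_irls,dfmax solver controls passed to
#'   [coxnet_path()]; when `dfmax` truncates a fold's path, the lambda
#'   search is restricted to values computed in every fold.
#' @return A `cv_coxnet` object: `lambda`, per-fold deviance matrix,
#'   `cvm` (mean), `cvse`, `lambda_min`, `nonzero_min` (SNP ids selected
#'   at `lambda_min`), `folds`, and the full-data `path`.
#' @export
cv_coxnet <- function(X, time, event, alpha = 1, k = 3, lambda = NULL,
                      fold_seed = 1L, penalty_free_idx = integer(0),
                      n_lambda = 100, min_ratio = NULL, max_redraw = 20L,
                      tol_cd = 1e-8, tol_irls = 1e-8, dfmax = NULL) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(lambda)) {
    lambda <- lambda_grid(X, time, event, alpha, n_lambda, min_ratio)
  }
  lambda <- as.numeric(lambda)

  folds <- NULL
  for (r in 0:max_redraw) {
    cand <- withr::with_seed(as.integer(fold_seed) + r * 1000003L,
                             sample(rep(seq_len(k), length.out = n)))
    ok <- all(vapply(seq_len(k),
                     function(f) sum(event[cand != f]) >= 1, logical(1)))
    if (ok) {
      folds <- cand
      break
    }
  }
  if (is.null(folds)) {
    stop("could not draw folds with events in every training set",
         call. = FALSE)
  }

  prep_full <- coxnet_prep(X, time, event)
  dev <- matrix(NA_real_, k, length(lambda))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- coxnet_path(X[tr, , drop = FALSE], time[tr], event[tr],
                       alpha = alpha, lambda = lambda,
                       penalty_free_idx = penalty_free_idx,
                       tol_cd = tol_cd, tol_irls = tol_irls, dfmax = dfmax)
    prep_tr <- coxnet_prep(X[tr, , drop = FALSE], time[tr], event[tr])
    for (l in seq_along(fit$lambda)) {
      b <- fit$beta[, l]
      # eta = X b up to an additive constant, to which the partial
      # likelihood is invariant; reconstruct from each set's standardization
      ll_full <- cox_breslow_loglik_cpp(
        drop(prep_full$Z %*% (b * prep_full$scale)),
        prep_full$event, prep_full$uid, prep_full$K
      )
      ll_tr <- cox_breslow_loglik_cpp(
        drop(prep_tr$Z %*% (b * prep_tr$scale)),
        prep_tr$event, prep_tr$uid, prep_tr$K
      )
      dev[f, l] <- -2 * (ll_full - ll_tr)
    }
  }
  # restrict to lambdas computed in every fold (dfmax may truncate)
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2, stats::sd) / sqrt(k)
  valid <- which(!is.na(cvm))
  if (!length(valid)) stop("no lambda computed in every fold", call. = FALSE)
  imin <- valid[which.min(cvm[valid])]
  full_path <- coxnet_path(X, time, event, alpha = alpha,
                           lambda = lambda[seq_len(max(valid))],
                           penalty_free_idx = penalty_free_idx,
                           tol_cd = tol_cd, tol_irls = tol_irls)
  imin_full <- min(imin, ncol(full_path$beta))
  nz <- rownames(full_path$beta)[full_path$beta[, imin_full] != 0]
  structure(list(
    lambda = lambda, dev = dev, cvm = cvm, cvse = cvse,
    lambda_min = lambda[imin], index_min = imin, nonzero_min = nz,
    folds = folds, alpha = alpha, path = full_path
  ), class = "cv_coxnet")
}

#' @export
print.cv_coxnet <- function(x, ...) {
  cat(sprintf(
    "cv_coxnet: alpha = %.2f, lambda_min = %.4g, %d nonzero at minimum\n",
    x$alpha, x$lambda_min, length(x$nonzero_min)))
  invisible(x)
}
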