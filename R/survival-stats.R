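#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with Greenwood standard errors.  The median is
#' the smallest time at which the estimated survival drops to 0.5 or
#' below (`NA` when never reached); its confidence interval is read off
#' the pointwise Greenwood band.
#'
#' @param time follow-up times (days), non-negative.
#' @param event 0/1 event indicators.
#' @param conf_level confidence level for pointwise intervals.
#' @return A `survival_curve`: list with a `table` (time, n_risk, n_event,
#'   n_censor, surv, se, lower, upper), `median`, `median_ci`, `n`.
#' @export
km <- function(time, event, conf_level = 0.95) {
  keep <- !is.na(time) & !is.na(event)
  time <- time[keep]; event <- event[keep]
  if (!length(time)) stop("no usable observations", call. = FALSE)
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  n <- length(time)
  ut <- unique(time)
  uid <- match(time, ut)
  d <- tabulate(uid)                       # leaving at each time
  nev <- vapply(split(event, uid), sum, numeric(1))
  n_risk <- n - c(0, cumsum(d))[seq_along(ut)]
  surv <- cumprod(1 - nev / n_risk)
  gw <- cumsum(ifelse(n_risk > nev, nev / (n_risk * (n_risk - nev)), 0))
  se <- surv * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lower <- pmax(0, surv - z * se)
  upper <- pmin(1, surv + z * se)
  tab <- data.frame(time = ut, n_risk = n_risk, n_event = nev,
                    n_censor = d - nev, surv = surv, se = se,
                    lower = lower, upper = upper)
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
  med_lo <- if (any(upper <= 0.5)) ut[which(upper <= 0.5)[1]] else NA_real_
  med_hi <- if (any(lower <= 0.5)) ut[which(lower <= 0.5)[1]] else NA_real_
  structure(list(table = tab, median = med,
                 median_ci = c(lower = med_lo, upper = med_hi), n = n),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, sum(x$table$n_event),
              ifelse(is.na(x$median), "not reached", format(x$median))))
  invisible(x)
}

#' Evaluate a survival curve at arbitrary times
#'
#' @param curve a `survival_curve` from [km()].
#' @param times times at which to evaluate (step function, right
#'   continuous).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(curve, times) {
  step_at(curve$table$time, curve$table$surv, times, before = 1)
}

# right-continuous step lookup; value `before` left of the first step
step_at <- function(xs, ys, t, before = 1) {
  idx <- findInterval(t, xs)
  out <- c(before, ys)[idx + 1]
  out
}

# left limit of a step function (value strictly before t)
step_before <- function(xs, ys, t, before = 1) {
  idx <- findInterval(t, xs, left.open = TRUE)
  c(before, ys)[idx + 1]
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank chi-square comparing survival across
#' groups, with `df = groups - 1`.
#'
#' @param time,event as in [km()].
#' @param group group labels (2 or more non-empty groups).
#' @return List with `statistic`, `df`, `p`, `obs`, `exp` per group.
#' @export
logrank <- function(time, event, group) {
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- event[keep]
  group <- factor(group[keep])
  group <- droplevels(group)
  G <- nlevels(group)
  if (G < 2) stop("log-rank test needs at least 2 groups", call. = FALSE)
  ord <- order(time)
  res <- logrank_core(time[ord], event[ord], as.integer(group)[ord], G)
  list(statistic = res$stat, df = G - 1,
       p = stats::pchisq(res$stat, G - 1, lower.tail = FALSE),
       obs = stats::setNames(res$obs, levels(group)),
       exp = stats::setNames(res$exp, levels(group)))
}

# log-rank machinery on time-sorted data; group is integer 1..G
logrank_core <- function(stime, sevent, sgroup, G) {
  n <- length(stime)
  ut_first <- !duplicated(stime)
  uid <- cumsum(ut_first)
  K <- uid[n]
  leaving <- tabulate(uid, K)
  nrisk_tot <- n - c(0, cumsum(leaving))[seq_len(K)]
  dg <- matrix(0, K, G)
  ng <- matrix(0, K, G)
  didx <- which(sevent == 1)
  for (g in seq_len(G)) {
    ing <- sgroup == g
    cnt <- tabulate(uid[ing], K)
    ng[, g] <- sum(ing) - c(0, cumsum(cnt))[seq_len(K)]
    dg[, g] <- tabulate(uid[didx][sgroup[didx] == g], K)
  }
  d <- rowSums(dg)
  use <- d > 0
  dg <- dg[use, , drop = FALSE]; ng <- ng[use, , drop = FALSE]
  d <- d[use]; nr <- nrisk_tot[use]
  E <- d * ng / nr
  U <- colSums(dg - E)
  vfac <- ifelse(nr > 1, d * (nr - d) / (nr - 1), 0)
  V <- matrix(0, G, G)
  for (g in seq_len(G)) {
    for (h in seq_len(g)) {
      pg <- ng[, g] / nr; ph <- ng[, h] / nr
      V[g, h] <- V[h, g] <- sum(vfac * pg * ((g == h) - ph))
    }
  }
  sub <- seq_len(G - 1)
  Vs <- V[sub, sub, drop = FALSE]
  stat <- tryCatch(
    drop(t(U[sub]) %*% solve(Vs, U[sub])),
    error = function(e) {
      drop(t(U[sub]) %*% MASS_ginv(Vs) %*% U[sub])
    }
  )
  list(stat = as.numeric(stat), obs = colSums(dg), exp = colSums(E))
}

# Moore-Penrose inverse via eigendecomposition (symmetric input)
MASS_ginv <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1e-300)
  if (!any(pos)) return(matrix(0, nrow(M), ncol(M)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# ---------------------------------------------------------------------------
# Cox proportional hazards by Newton-Raphson
# ---------------------------------------------------------------------------

# log partial likelihood, score and information on one stratum.
# tie_weights: Efron uses j/d within each tied death group, Breslow uses 0.
cox_derivs_stratum <- function(X, time, event, beta, ties) {
  ord <- order(time)
  X <- X[ord, , drop = FALSE]; time <- time[ord]; event <- event[ord]
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - mean(eta)                  # stabilize exp()
  w <- exp(eta)
  ut_first <- !duplicated(time)
  uid <- cumsum(ut_first)
  K <- uid[n]
  revcum <- function(v) rev(cumsum(rev(v)))
  agg <- function(v) {
    out <- numeric(K); s <- rowsum(v, uid); out[as.integer(rownames(s))] <- s
    out
  }
  S0 <- revcum(agg(w))                           # sum exp(eta) over risk set
  S1 <- apply(X * w, 2, function(col) revcum(agg(col)))
  S1 <- matrix(S1, nrow = K)
  # S2 upper-triangular pairs
  S2 <- array(0, c(K, p, p))
  for (a in seq_len(p)) {
    for (b in a:p) {
      v <- revcum(agg(w * X[, a] * X[, b]))
      S2[, a, b] <- v; S2[, b, a] <- v
    }
  }
  didx <- which(event == 1)
  if (!length(didx)) {
    return(list(loglik = 0, grad = numeric(p), info = matrix(0, p, p),
                nevent = 0))
  }
  duid <- uid[didx]
  dcount <- tabulate(duid, K)
  loglik <- sum(eta[didx])
  grad <- colSums(X[didx, , drop = FALSE])
  info <- matrix(0, p, p)
  # untied death times (the common case), fully vectorized
  singles <- which(dcount == 1L)
  if (length(singles)) {
    D <- S0[singles]
    U <- S1[singles, , drop = FALSE] / D
    loglik <- loglik - sum(log(D))
    grad <- grad - colSums(U)
    for (a in seq_len(p)) {
      for (b in a:p) {
        v <- sum(S2[singles, a, b] / D)
        info[a, b] <- info[a, b] + v
        if (b > a) info[b, a] <- info[b, a] + v
      }
    }
    info <- info - crossprod(U)
  }
  # tied death times: Efron fractions (Breslow uses 0)
  for (k in which(dcount > 1L)) {
    d <- dcount[k]
    rows <- didx[duid == k]
    frac <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    ed <- sum(w[rows])
    edx <- colSums(w[rows] * X[rows, , drop = FALSE])
    edxx <- crossprod(sqrt(w[rows]) * X[rows, , drop = FALSE])
    for (j in seq_len(d)) {
      f <- frac[j]
      D <- S0[k] - f * ed
      xb <- (S1[k, ] - f * edx) / D
      loglik <- loglik - log(D)
      grad <- grad - xb
      info <- info + (S2[k, , ] - f * edxx) / D - tcrossprod(xb)
    }
  }
  list(loglik = loglik, grad = grad, info = info, nevent = length(didx))
}

cox_derivs <- function(X, time, event, beta, ties, strata) {
  p <- ncol(X)
  out <- list(loglik = 0, grad = numeric(p), info = matrix(0, p, p),
              nevent = 0)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (!length(idx)) next
    d <- cox_derivs_stratum(X[idx, , drop = FALSE], time[idx], event[idx],
                            beta, ties)
    out$loglik <- out$loglik + d$loglik
    out$grad <- out$grad + d$grad
    out$info <- out$info + d$info
    out$nevent <- out$nevent + d$nevent
  }
  out
}

#' Cox proportional hazards regression
#'
#' Maximizes the Cox log partial likelihood by Newton-Raphson with
#' step-halving.  Ties are handled by the Efron approximation by default
#' (Breslow optional); with no tied event times the two coincide exactly.
#' Convergence is declared when the score sup-norm falls below `grad_tol`
#' or the relative log-likelihood change falls below `ll_tol`.  The
#' covariance matrix is the inverse observed information.
#'
#' @param X numeric design matrix (no intercept; rows with missing values
#'   are dropped and counted).
#' @param time,event survival outcome (days, 0/1).
#' @param ties `"efron"` or `"breslow"`.
#' @param strata optional factor of baseline-hazard strata.
#' @param grad_tol,ll_tol convergence tolerances.
#' @param max_iter iteration cap.
#' @param conf_level confidence level for hazard-ratio intervals.
#' @return A `cox_fit` object: coefficients, covariance, hazard ratios
#'   with confidence intervals, per-coefficient Wald z/p, joint Wald test,
#'   log partial likelihood at the estimate and at zero, convergence and
#'   separation flags, and the Breslow baseline cumulative hazard per
#'   stratum (for survival prediction).
#' @export
cox_fit <- function(X, time, event, ties = c("efron", "breslow"),
                    strata = NULL, grad_tol = 1e-9, ll_tol = 1e-10,
                    max_iter = 50, conf_level = 0.95) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(strata)) strata <- factor(rep("all", length(time)))
  strata <- factor(strata)
  keep <- stats::complete.cases(X) & !is.na(time) & !is.na(event) &
    !is.na(strata)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  strata <- droplevels(strata[keep])
  if (sum(event) < 1) stop("no events in the data", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("collinear design matrix", call. = FALSE)
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  p <- ncol(X)
  beta <- numeric(p)
  dv <- cox_derivs(Xc, time, event, beta, ties, strata)
  ll0 <- dv$loglik
  converged <- FALSE
  separation <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    step <- tryCatch(solve(dv$info, dv$grad), error = function(e) NULL)
    if (is.null(step)) {
      separation <- TRUE
      break
    }
    new_beta <- beta + step
    new_dv <- cox_derivs(Xc, time, event, new_beta, ties, strata)
    halves <- 0
    # require descent up to float noise; a strict test would freeze the
    # iteration near the optimum and leave the score at ~1e-6
    slack <- 1e-10 * (abs(dv$loglik) + 1)
    while (new_dv$loglik < dv$loglik - slack && halves < 25) {
      new_beta <- (beta + new_beta) / 2
      new_dv <- cox_derivs(Xc, time, event, new_beta, ties, strata)
      halves <- halves + 1
    }
    rel <- abs(new_dv$loglik - dv$loglik) / (abs(dv$loglik) + 0.1)
    beta <- new_beta
    dv <- new_dv
    # a log-likelihood stall only counts as convergence once the score
    # is already small; otherwise take another (cheap) Newton step
    if (max(abs(dv$grad)) < grad_tol ||
        (rel < ll_tol && max(abs(dv$grad)) < 1e-8)) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 20) {
      separation <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  V <- tryCatch(solve(dv$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(V), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  wald_stat <- tryCatch(drop(t(beta) %*% solve(V, beta)),
                        error = function(e) NA_real_)
  fit <- structure(list(
    coef = stats::setNames(beta, colnames(X)),
    var = V,
    se = stats::setNames(se, colnames(X)),
    hr = exp(beta),
    ci = cbind(lower = exp(beta - z * se), upper = exp(beta + z * se)),
    zstat = beta / se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    wald = list(statistic = wald_stat, df = p,
                p = stats::pchisq(wald_stat, p, lower.tail = FALSE)),
    loglik = dv$loglik, loglik_null = ll0,
    n = length(time), nevent = dv$nevent, n_dropped = n_dropped,
    iter = iter, converged = converged, separation = separation,
    score_max = max(abs(dv$grad)),
    ties = ties, center = ctr
  ), class = "cox_fit")
  fit$baseline <- cox_baseline(Xc, time, event, beta, strata)
  fit$strata_levels <- levels(strata)
  fit
}

# Breslow baseline cumulative hazard per stratum, at centered covariates
cox_baseline <- function(Xc, time, event, beta, strata) {
  eta <- drop(Xc %*% beta)
  w <- exp(eta)
  lapply(stats::setNames(levels(strata), levels(strata)), function(s) {
    idx <- which(strata == s)
    ti <- time[idx]; ev <- event[idx]; wi <- w[idx]
    ord <- order(ti)
    ti <- ti[ord]; ev <- ev[ord]; wi <- wi[ord]
    ut_first <- !duplicated(ti)
    uid <- cumsum(ut_first)
    K <- max(uid)
    agg <- function(v) {
      out <- numeric(K); s <- rowsum(v, uid)
      out[as.integer(rownames(s))] <- s; out
    }
    S0 <- rev(cumsum(rev(agg(wi))))
    d <- agg(as.numeric(ev))
    keep <- d > 0
    list(time = ti[ut_first][keep], cumhaz = cumsum(d[keep] / S0[keep]))
  })
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit: n = %d, events = %d, %s ties, %s\n",
              x$n, x$nevent, x$ties,
              if (x$converged) sprintf("converged in %d iterations", x$iter)
              else "DID NOT CONVERGE"))
  tab <- data.frame(coef = x$coef, HR = x$hr, lower = x$ci[, 1],
                    upper = x$ci[, 2], p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Predict survival probabilities from a Cox fit
#'
#' Uses the Breslow baseline cumulative hazard:
#' `S(t | x) = exp(-H0(t) * exp((x - xbar)'beta))`.
#'
#' @param fit a [cox_fit()].
#' @param X_new covariate matrix for new patients (same columns as fit).
#' @param times evaluation times.
#' @param strata_new stratum per new patient (defaults to the single
#'   stratum of an unstratified fit).
#' @return Matrix of survival probabilities, patients x times.
#' @export
cox_predict_survival <- function(fit, X_new, times, strata_new = NULL) {
  X_new <- as.matrix(X_new)
  if (is.null(strata_new)) {
    if (length(fit$strata_levels) > 1) {
      stop("stratified fit: strata_new required", call. = FALSE)
    }
    strata_new <- rep(fit$strata_levels, nrow(X_new))
  }
  eta <- drop(sweep(X_new, 2, fit$center) %*% fit$coef)
  out <- matrix(NA_real_, nrow(X_new), length(times))
  for (s in unique(strata_new)) {
    bl <- fit$baseline[[as.character(s)]]
    H0 <- step_at(bl$time, bl$cumhaz, times, before = 0)
    rows <- which(strata_new == s)
    out[rows, ] <- exp(-outer(exp(eta[rows]), H0))
  }
  out
}

#' Covariate-adjusted genotype association with a survival endpoint
#'
#' Fits a Cox model with the requested genetic encoding of one SNP plus
#' clinical covariates, and reports hazard ratios, confidence intervals
#' and the across-genotype Wald test (2 df for the codominant model, 1 df
#' for dominant/recessive).  Patients with a missing genotype, endpoint or
#' covariate are excluded for that SNP (complete-case, with the exclusion
#' count reported).
#'
#' @param gm a [genotype_matrix()].
#' @param snp_id SNP to test.
#' @param model `"codominant"`, `"dominant"` or `"recessive"`.
#' @param clinical clinical data.frame (see [read_clinical()]), rows
#'   aligned with `gm` patients by `patient_id`.
#' @param covariates character vector of clinical column names to adjust
#'   for (may be empty).
#' @param endpoint `"pfs"` or `"os"`.
#' @param strata optional clinical column used as baseline-hazard strata
#'   (e.g. cohort in pooled analyses).
#' @param flip swap allele roles before encoding (see [encode()]).
#' @return A one-row data.frame (two rows for codominant): snp_id, gene,
#'   model, term, `hr`, `ci_lower`, `ci_upper`, `coef_p`, `wald_p`,
#'   `wald_df`, genotype group sizes `n_hom_major`, `n_het`,
#'   `n_hom_minor`, `n_used`, and an `inestimable` flag.
#' @export
genotype_association <- function(gm, snp_id,
                                 model = c("codominant", "dominant",
                                           "recessive"),
                                 clinical, covariates = character(0),
                                 endpoint = c("pfs", "os"),
                                 strata = NULL, flip = FALSE) {
  model <- match.arg(model)
  endpoint <- match.arg(endpoint)
  idx <- match(gm$patient_ids, clinical$patient_id)
  if (anyNA(idx)) stop("clinical table lacks some genotyped patients",
                       call. = FALSE)
  cl <- clinical[idx, , drop = FALSE]
  time <- cl[[paste0(endpoint, "_time")]]
  event <- cl[[paste0(endpoint, "_event")]]
  enc <- encode(gm, snp_id, if (model == "codominant") "codominant" else model,
                flip = flip)
  enc <- as.matrix(enc)
  colnames(enc) <- if (model == "codominant") c("het", "hom_minor") else model
  covX <- NULL
  if (length(covariates)) {
    miss <- setdiff(covariates, names(cl))
    if (length(miss)) stop("unknown covariate(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    covX <- stats::model.matrix(
      ~., data = cl[, covariates, drop = FALSE]
    )[, -1, drop = FALSE]
  }
  str_vec <- if (!is.null(strata)) factor(cl[[strata]]) else NULL
  Xall <- cbind(enc, covX)
  keep <- stats::complete.cases(Xall) & !is.na(time) & !is.na(event)
  if (!is.null(str_vec)) keep <- keep & !is.na(str_vec)
  g <- encode(gm, snp_id, "additive", flip = flip)
  gsz <- c(n_hom_major = sum(g[keep] == 0), n_het = sum(g[keep] == 1),
           n_hom_minor = sum(g[keep] == 2))
  snp_row <- gm$snps[match(snp_id, gm$snps$snp_id), ]
  base <- data.frame(snp_id = snp_id, gene = snp_row$gene, model = model,
                     endpoint = endpoint, stringsAsFactors = FALSE)
  terms <- colnames(enc)
  empty <- switch(model,
    codominant = any(gsz == 0),
    dominant   = gsz[["n_hom_major"]] == 0 ||
                 (gsz[["n_het"]] + gsz[["n_hom_minor"]]) == 0,
    recessive  = gsz[["n_hom_minor"]] == 0 ||
                 (gsz[["n_hom_major"]] + gsz[["n_het"]]) == 0
  )
  make_na <- function(reason) {
    out <- merge(base, data.frame(term = terms))
    out$hr <- NA_real_; out$ci_lower <- NA_real_; out$ci_upper <- NA_real_
    out$coef_p <- NA_real_; out$wald_p <- NA_real_
    out$wald_df <- length(terms)
    out[names(gsz)] <- as.list(gsz)
    out$n_used <- sum(keep)
    out$inestimable <- TRUE
    out$note <- reason
    out
  }
  if (empty) return(make_na("empty genotype group"))
  fit <- tryCatch(
    cox_fit(Xall[keep, , drop = FALSE], time[keep], event[keep],
            strata = if (!is.null(str_vec)) str_vec[keep] else NULL),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    return(make_na(if (is.null(fit)) "fit error" else "non-convergence"))
  }
  gidx <- seq_along(terms)
  Vg <- fit$var[gidx, gidx, drop = FALSE]
  bg <- fit$coef[gidx]
  wstat <- tryCatch(drop(t(bg) %*% solve(Vg, bg)), error = function(e) NA)
  out <- merge(base, data.frame(term = terms), sort = FALSE)
  out$hr <- fit$hr[gidx]
  out$ci_lower <- fit$ci[gidx, 1]
  out$ci_upper <- fit$ci[gidx, 2]
  out$coef_p <- fit$p[gidx]
  out$wald_p <- stats::pchisq(wstat, length(gidx), lower.tail = FALSE)
  out$wald_df <- length(gidx)
  out[names(gsz)] <- as.list(gsz)
  out$n_used <- sum(keep)
  out$inestimable <- FALSE
  out$note <- ""
  out
}
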