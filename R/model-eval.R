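#' Inverse-probability-of-censoring weighted Brier score
#'
#' Brier score at horizon `t` for right-censored data, with the censoring
#' distribution `G` estimated by the Kaplan-Meier estimator on the
#' censoring indicator.  Patients with an event before `t` contribute
#' `(0 - S_hat)^2 / G(T_i-)` (left limit), patients still at risk past
#' `t` contribute `(1 - S_hat)^2 / G(t)`, and patients censored before
#' `t` contribute 0.  With no censoring this reduces exactly to the mean
#' squared error of the predicted survival probabilities against the
#' survival status at `t`.
#'
#' @param predicted_survival predicted survival probability at `t`, one
#'   per patient, in `[0, 1]`.
#' @param time,event observed follow-up and 0/1 event indicator.
#' @param t evaluation time.
#' @param cens_km optional precomputed censoring curve ([km()] of
#'   `1 - event`), reused across calls on the same data.
#' @return The weighted Brier score.
#' @export
ipcw_brier <- function(predicted_survival, time, event, t,
                       cens_km = NULL) {
  if (any(predicted_survival < 0 | predicted_survival > 1, na.rm = TRUE)) {
    stop("predictions must be probabilities in [0, 1]", call. = FALSE)
  }
  n <- length(time)
  if (is.null(cens_km)) cens_km <- km(time, 1 - event)
  Gt <- km_surv_at(cens_km, t)
  Gm <- step_before(cens_km$table$time, cens_km$table$surv, time, before = 1)
  died <- time <= t & event == 1
  atrisk <- time > t
  if (any(atrisk) && Gt <= 0) {
    stop("censoring survival G(t) is zero at the requested horizon",
         call. = FALSE)
  }
  if (any(died & Gm <= 0)) {
    stop("censoring survival is zero before an event time", call. = FALSE)
  }
  contrib <- numeric(n)
  contrib[died] <- (0 - predicted_survival[died])^2 / Gm[died]
  contrib[atrisk] <- (1 - predicted_survival[atrisk])^2 / Gt
  mean(contrib)
}

# build a design matrix for a model spec: covariates + encoded SNPs,
# missing genotype indicators imputed to their mean
pec_design <- function(spec, gm, clinical) {
  blocks <- list()
  if (length(spec$covariates)) {
    blocks$cov <- stats::model.matrix(
      ~., data = clinical[, spec$covariates, drop = FALSE]
    )[, -1, drop = FALSE]
  }
  if (length(spec$snps)) {
    for (i in seq_along(spec$snps)) {
      s <- spec$snps[[i]]
      enc <- as.matrix(encode(gm, s$snp_id, s$model))
      colnames(enc) <- paste0(s$snp_id, "_",
                              if (ncol(enc) == 2) c("het", "hom") else s$model)
      for (j in seq_len(ncol(enc))) {
        x <- enc[, j]
        if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
        enc[, j] <- x
      }
      blocks[[length(blocks) + 1L]] <- enc
    }
  }
  if (!length(blocks)) return(NULL)
  do.call(cbind, blocks)
}

#' Bootstrapped prediction error curves for competing survival models
#'
#' For each bootstrap resample (with replacement), each model is fitted
#' on the in-bag patients and its IPCW Brier score is evaluated on the
#' out-of-bag patients over the time grid; the mean out-of-bag curve per
#' model is reported.  A model with `covariates = NULL, snps = NULL` (or
#' `NULL`) is the null model: the in-bag marginal Kaplan-Meier curve used
#' as every patient's prediction.
#'
#' @param model_specs named list of model specifications; each is `NULL`
#'   (null model) or a list with elements `covariates` (clinical column
#'   names) and `snps` (list of `list(snp_id =, model =)`).
#' @param gm a [genotype_matrix()].
#' @param clinical clinical table aligned with `gm`.
#' @param endpoint `"pfs"` or `"os"`.
#' @param time_grid evaluation times (days).
#' @param bootstrap_B number of resamples, default 100.
#' @param seed integer seed.
#' @param max_skip_frac error when more than this fraction of resamples
#'   fails.
#' @return A `prediction_error_curve`: `time`, `brier` (model x time mean
#'   out-of-bag scores), `B_effective`, `skips`.
#' @export
pec_compare <- function(model_specs, gm, clinical,
                        endpoint = c("pfs", "os"), time_grid,
                        bootstrap_B = 100, seed = 1L,
                        max_skip_frac = 0.10) {
  endpoint <- match.arg(endpoint)
  if (!length(names(model_specs)) || any(names(model_specs) == "")) {
    stop("model_specs must be a named list", call. = FALSE)
  }
  idx <- match(gm$patient_ids, clinical$patient_id)
  cl <- clinical[idx, , drop = FALSE]
  time <- cl[[paste0(endpoint, "_time")]]
  event <- cl[[paste0(endpoint, "_event")]]
  designs <- lapply(model_specs, function(sp) {
    if (is.null(sp)) NULL else pec_design(sp, gm, cl)
  })
  n <- length(time)
  M <- length(model_specs)
  acc <- matrix(0, M, length(time_grid),
                dimnames = list(names(model_specs), NULL))
  used <- 0L
  skips <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(bootstrap_B)) {
      inbag <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(inbag))
      if (length(oob) < 5 || sum(event[inbag]) < 1 ||
          sum(event[oob]) < 1) {
        skips <- skips + 1L
        next
      }
      stopifnot(length(intersect(unique(inbag), oob)) == 0)
      cens <- km(time[oob], 1 - event[oob])
      scores <- matrix(NA_real_, M, length(time_grid))
      ok <- TRUE
      for (m in seq_len(M)) {
        X <- designs[[m]]
        preds <- if (is.null(X)) {
          fitk <- km(time[inbag], event[inbag])
          matrix(rep(km_surv_at(fitk, time_grid), each = length(oob)),
                 nrow = length(oob))
        } else {
          fit <- tryCatch(
            cox_fit(X[inbag, , drop = FALSE], time[inbag], event[inbag]),
            error = function(e) NULL
          )
          if (is.null(fit) || !fit$converged) {
            ok <- FALSE
            break
          }
          cox_predict_survival(fit, X[oob, , drop = FALSE], time_grid)
        }
        scores[m, ] <- vapply(seq_along(time_grid), function(ti) {
          ipcw_brier(preds[, ti], time[oob], event[oob], time_grid[ti],
                     cens_km = cens)
        }, numeric(1))
      }
      if (!ok) {
        skips <- skips + 1L
        next
      }
      acc <- acc + scores
      used <- used + 1L
    }
  })
  if (bootstrap_B > 0 && skips / bootstrap_B > max_skip_frac) {
    stop(sprintf("%d of %d bootstrap resamples failed", skips, bootstrap_B),
         call. = FALSE)
  }
  structure(list(time = time_grid, brier = acc / max(used, 1),
                 B_effective = used, skips = skips),
            class = "prediction_error_curve")
}

#' @export
print.prediction_error_curve <- function(x, ...) {
  cat(sprintf("prediction error curves: %d models, %d effective resamples\n",
              nrow(x$brier), x$B_effective))
  invisible(x)
}

#' Trapezoidal integrated Brier score
#'
#' @param pec a `prediction_error_curve`.
#' @return Named vector of integrated scores (one per model), normalized
#'   by the grid span.
#' @export
integrated_brier <- function(pec) {
  t <- pec$time
  if (length(t) < 2) return(pec$brier[, 1])
  w <- diff(t)
  apply(pec$brier, 1, function(b) {
    sum((b[-1] + b[-length(b)]) / 2 * w) / (max(t) - min(t))
  })
}
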