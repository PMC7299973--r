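#' Stability selection by repeated subsampled cross-validated penalized Cox
#'
#' Repeats, `n_repeats` times: draw `floor(subsample * N)` patients
#' without replacement; run [cv_coxnet()] on their genotypes against the
#' PFS endpoint (fresh fold split each repeat); record the SNPs in the
#' nonzero set at `lambda_min`.  Selection counts over repeats form the
#' profile.  Genotypes enter as additive 0/1/2 codes with missing calls
#' imputed to each SNP's mean dosage.
#'
#' Per-repeat seeds are derived deterministically from `master_seed`
#' (subsample draw: `master_seed + r`; fold split: `master_seed +
#' n_repeats + r`), so results are reproducible and independent of any
#' parallel scheduling.
#'
#' @param gm a [genotype_matrix()] (post discovery QC).
#' @param clinical clinical table aligned by `patient_id` with PFS
#'   endpoints.
#' @param alpha elastic-net mixing (1 = LASSO, 0.5 = the elastic-net
#'   variant used for discovery).
#' @param n_repeats number of random subsets, default 1000.
#' @param subsample fraction of patients per subset, default 0.9.
#' @param k cross-validation folds, default 3.
#' @param master_seed integer master seed.
#' @param n_lambda path length per cross-validation (coarser than a
#'   single-fit path; the selected set at `lambda_min` is what matters).
#' @param dfmax path-size bound per fit: the regularization path stops
#'   once a solution exceeds this many nonzero SNPs.  Defaults to a
#'   third of the subsample size — the cross-validated deviance optimum
#'   for a germline panel lies far below the near-saturated tail, which
#'   is both unidentifiable and the most expensive stretch of the path.
#' @param max_skip_frac abort when more than this fraction of repeats
#'   fail (e.g. no events in a training fold after redraws).
#' @return A `selection_profile`: per-SNP selection `count`, `frequency`,
#'   per-repeat nonzero-set sizes, skips, and the run parameters.
#' @export
run_stability <- function(gm, clinical, alpha, n_repeats = 1000,
                          subsample = 0.9, k = 3, master_seed = 1L,
                          n_lambda = 50, dfmax = NULL,
                          max_skip_frac = 0.05) {
  idx <- match(gm$patient_ids, clinical$patient_id)
  if (anyNA(idx)) stop("clinical table lacks some genotyped patients",
                       call. = FALSE)
  time <- clinical$pfs_time[idx]
  event <- clinical$pfs_event[idx]
  X <- impute_mean_dosage(gm$codes)
  n <- nrow(X)
  m <- floor(subsample * n)
  if (is.null(dfmax)) dfmax <- max(25L, floor(m / 3))
  counts <- stats::setNames(integer(ncol(X)), colnames(X))
  sizes <- integer(0)
  skips <- 0L
  master_seed <- as.integer(master_seed)
  for (r in seq_len(n_repeats)) {
    rows <- withr::with_seed(master_seed + r, sample.int(n, m))
    res <- tryCatch(
      cv_coxnet(X[rows, , drop = FALSE], time[rows], event[rows],
                alpha = alpha, k = k,
                fold_seed = master_seed + n_repeats + r,
                n_lambda = n_lambda, dfmax = dfmax,
                tol_cd = 1e-7, tol_irls = 1e-7),
      error = function(e) NULL
    )
    if (is.null(res)) {
      skips <- skips + 1L
      next
    }
    counts[res$nonzero_min] <- counts[res$nonzero_min] + 1L
    sizes <- c(sizes, length(res$nonzero_min))
  }
  if (n_repeats > 0 && skips / n_repeats > max_skip_frac) {
    stop(sprintf("%d of %d stability repeats failed", skips, n_repeats),
         call. = FALSE)
  }
  structure(list(
    alpha = alpha, n_repeats = n_repeats, subsample = subsample, k = k,
    master_seed = master_seed, count = counts,
    frequency = if (n_repeats > 0) counts / n_repeats else counts * 0,
    repeat_sizes = sizes, mean_size = if (length(sizes)) mean(sizes) else 0,
    skips = skips
  ), class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf(
    "selection profile: alpha = %.2f, %d repeats, mean set size %.1f, top frequency %.2f\n",
    x$alpha, x$n_repeats, x$mean_size,
    if (length(x$count)) max(x$frequency) else 0))
  invisible(x)
}

#' Aggregate candidate SNPs from two selection profiles
#'
#' Union of the LASSO profile's SNPs selected in strictly more than
#' `th_lasso * n_repeats` repeats and the elastic-net profile's SNPs
#' selected in at least `th_en * n_repeats` repeats (the inclusivity of
#' the two thresholds deliberately differs: strict for LASSO, inclusive
#' for elastic net).
#'
#' @param profile_lasso,profile_en `selection_profile`s computed on the
#'   same SNP universe.
#' @param th_lasso,th_en frequency thresholds (defaults 0.25 and 0.70).
#' @return Character vector of candidate SNP ids (in SNP-universe order).
#' @export
candidate_set <- function(profile_lasso, profile_en,
                          th_lasso = 0.25, th_en = 0.70) {
  if (!identical(names(profile_lasso$count), names(profile_en$count))) {
    stop("profiles computed on different SNP universes", call. = FALSE)
  }
  ids <- names(profile_lasso$count)
  sel_l <- profile_lasso$count > th_lasso * profile_lasso$n_repeats
  sel_e <- profile_en$n_repeats > 0 &
    profile_en$count >= th_en * profile_en$n_repeats
  ids[sel_l | sel_e]
}

#' Remove candidates departing from Hardy-Weinberg equilibrium
#'
#' Drops candidates whose exact HWE p-value is `<= p_floor` (the rule is
#' that a retained SNP requires p strictly above the floor).
#'
#' @param candidates candidate SNP ids.
#' @param gm the [genotype_matrix()] holding their genotypes.
#' @param p_floor HWE p-value floor, default 1e-4.
#' @return Character vector of retained candidates, with attribute
#'   `dropped` listing the eliminated ids.
#' @export
post_hwe_filter <- function(candidates, gm, p_floor = 1e-4) {
  if (!all(candidates %in% gm$snps$snp_id)) {
    stop("candidates must be SNPs of the genotype matrix", call. = FALSE)
  }
  if (!length(candidates)) {
    return(structure(character(0), dropped = character(0)))
  }
  p <- gm_hwe(gm_subset(gm, snps = candidates))
  keep <- p > p_floor
  structure(candidates[keep], dropped = candidates[!keep])
}

# mean-dosage imputation of missing genotype codes, per SNP
impute_mean_dosage <- function(codes) {
  X <- codes
  storage.mode(X) <- "double"
  nas <- colSums(is.na(X))
  for (j in which(nas > 0)) {
    x <- X[, j]
    m <- mean(x, na.rm = TRUE)
    if (is.nan(m)) m <- 0
    x[is.na(x)] <- m
    X[, j] <- x
  }
  X
}
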