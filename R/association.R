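#' Covariate-adjusted association scan over candidate SNPs
#'
#' Runs [genotype_association()] for every candidate under the requested
#' genetic models, optionally restricted to a clinical subgroup (e.g.
#' KRAS wild-type).  SNPs that are monomorphic in the (sub)cohort are
#' returned flagged inestimable rather than dropped.
#'
#' @param candidates SNP ids.
#' @param gm a [genotype_matrix()].
#' @param clinical clinical table.
#' @param covariates covariate column names for adjustment.
#' @param endpoint `"pfs"` or `"os"`.
#' @param models genetic models to fit.
#' @param subgroup optional named list of clinical `column = value`
#'   restrictions applied before fitting.
#' @param strata optional clinical column of baseline-hazard strata.
#' @return data.frame with one row per SNP x model term.
#' @export
adjusted_scan <- function(candidates, gm, clinical,
                          covariates = character(0),
                          endpoint = c("pfs", "os"),
                          models = c("codominant", "dominant", "recessive"),
                          subgroup = NULL, strata = NULL) {
  endpoint <- match.arg(endpoint)
  if (!length(candidates)) stop("no candidates to scan", call. = FALSE)
  for (cv in covariates) {
    if (all(is.na(clinical[[cv]]))) {
      stop("covariate entirely missing: ", cv, call. = FALSE)
    }
  }
  if (!is.null(subgroup)) {
    keep <- rep(TRUE, nrow(clinical))
    for (col in names(subgroup)) {
      keep <- keep & !is.na(clinical[[col]]) &
        clinical[[col]] == subgroup[[col]]
    }
    clinical <- clinical[keep, , drop = FALSE]
    gm <- gm_subset(gm, patients = intersect(gm$patient_ids,
                                             clinical$patient_id))
  }
  rows <- list()
  for (snp in candidates) {
    for (m in models) {
      rows[[length(rows) + 1L]] <- genotype_association(
        gm, snp, model = m, clinical = clinical, covariates = covariates,
        endpoint = endpoint, strata = strata
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation-corrected log-rank test for one SNP
#'
#' The raw p-value is the log-rank test across the SNP's genotype groups;
#' the corrected p-value is the fraction of `B` seeded permutations of
#' the genotype vector (survival data fixed) whose log-rank p-value is at
#' or below the observed one.  With `smoothed = TRUE` the add-one
#' estimate `(1 + #)/(1 + B)` is returned instead of the plain frequency.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_id SNP to test.
#' @param clinical clinical table.
#' @param endpoint `"pfs"` or `"os"`.
#' @param B number of permutations, default 10000.
#' @param seed integer seed.
#' @param smoothed use the add-one-smoothed frequency.
#' @return List with `raw_p`, `corrected_p`, `B`, `df`.
#' @export
permutation_corrected_logrank <- function(gm, snp_id, clinical,
                                          endpoint = c("pfs", "os"),
                                          B = 10000, seed = 1L,
                                          smoothed = FALSE) {
  endpoint <- match.arg(endpoint)
  idx <- match(gm$patient_ids, clinical$patient_id)
  time <- clinical[[paste0(endpoint, "_time")]][idx]
  event <- clinical[[paste0(endpoint, "_event")]][idx]
  g <- encode(gm, snp_id, "additive")
  keep <- !is.na(g) & !is.na(time) & !is.na(event)
  g <- g[keep]; time <- time[keep]; event <- event[keep]
  grp <- factor(g)
  G <- nlevels(grp)
  if (G < 2) stop("genotype has a single group; test undefined",
                  call. = FALSE)
  ord <- order(time)
  stime <- time[ord]; sevent <- event[ord]
  gint <- as.integer(grp)
  df <- G - 1
  obs <- logrank_core(stime, sevent, gint[ord], G)
  raw_p <- stats::pchisq(obs$stat, df, lower.tail = FALSE)
  hits <- withr::with_seed(as.integer(seed), {
    h <- 0L
    for (b in seq_len(B)) {
      pg <- sample(gint)
      st <- logrank_core(stime, sevent, pg[ord], G)$stat
      pb <- stats::pchisq(st, df, lower.tail = FALSE)
      if (pb <= raw_p) h <- h + 1L
    }
    h
  })
  corrected <- if (smoothed) (1 + hits) / (1 + B) else hits / B
  list(raw_p = raw_p, corrected_p = corrected, B = B, df = df)
}

#' Fisher's exact test for small r x c contingency tables
#'
#' Exact p-value by full enumeration of all tables with the observed
#' margins: the sum of the probabilities (multivariate hypergeometric) of
#' every table whose probability does not exceed the observed table's.
#' Supported up to 3 rows x 3 columns; larger tables are refused.
#'
#' @param table non-negative integer matrix.
#' @return The exact p-value.
#' @export
fisher_exact_rxc <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must hold non-negative integers", call. = FALSE)
  }
  if (nrow(tab) > 3 || ncol(tab) > 3) {
    stop("enumeration supported up to 3x3 tables only", call. = FALSE)
  }
  N <- sum(tab)
  if (N == 0) stop("empty table", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  logdenom <- lgamma(N + 1) - sum(lgamma(rs + 1)) - sum(lgamma(cs + 1))
  logp_table <- function(m) -(logdenom + sum(lgamma(m + 1)))
  obs <- logp_table(tab)
  r <- nrow(tab); cc <- ncol(tab)
  total <- 0
  cells <- matrix(0L, r, cc)
  recurse <- function(i, j, row_left, col_left) {
    if (i == r) {
      # last row forced by column margins
      if (any(col_left < 0)) return()
      cells[r, ] <<- col_left
      lp <- logp_table(cells)
      if (lp <= obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    if (j == cc) {
      # last cell of row i forced by the row margin
      v <- row_left
      if (v < 0 || v > col_left[cc]) return()
      cells[i, cc] <<- v
      recurse(i + 1L, 1L, rs[i + 1L], col_left - cells[i, ])
      return()
    }
    for (v in 0:min(row_left, col_left[j])) {
      cells[i, j] <<- v
      recurse(i, j + 1L, row_left - v, col_left)
    }
  }
  recurse(1L, 1L, rs[1], cs)
  min(1, total)
}

#' Pearson chi-square test for a contingency table
#'
#' Pearson chi-square with `df = (r - 1)(c - 1)`; for 2 x 2 tables the
#' Yates continuity correction is applied by default (matching the
#' convention that reproduces the cohort-characteristics table).
#'
#' @param table non-negative matrix with positive margins.
#' @param yates_for_2x2 apply Yates correction when the table is 2 x 2.
#' @return List with `statistic`, `df`, `p`.
#' @export
chisq_contingency <- function(table, yates_for_2x2 = TRUE) {
  tab <- as.matrix(table)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has a zero margin", call. = FALSE)
  }
  res <- suppressWarnings(
    stats::chisq.test(tab, correct = yates_for_2x2)
  )
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Pairwise linkage disequilibrium from unphased genotypes
#'
#' Two-locus haplotype frequencies are estimated by EM over the unphased
#' genotype pairs (the double-heterozygote class is split between the
#' coupling and repulsion phases by their current odds), starting from
#' linkage equilibrium.  Reports `D = p11 - pA*pB`, the scaled
#' `D' = |D| / Dmax`, and the haplotype correlation `r`.
#'
#' @param gm a [genotype_matrix()].
#' @param snp1,snp2 SNP ids (minor alleles are the counted alleles).
#' @param tol EM convergence tolerance on haplotype frequencies.
#' @param max_iter EM iteration cap.
#' @return An `ld_stats` list: `hap` (freqs of 11, 10, 01, 00), `D`,
#'   `Dprime`, `r`, `iter`, `loglik`, `n`.
#' @export
ld_pair <- function(gm, snp1, snp2, tol = 1e-10, max_iter = 1000) {
  g1 <- encode(gm, snp1, "additive")
  g2 <- encode(gm, snp2, "additive")
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  if (n < 2) stop("fewer than 2 patients with both SNPs called",
                  call. = FALSE)
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2) {
    stop("monomorphic SNP: LD undefined", call. = FALSE)
  }
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[g1[i] + 1, g2[i] + 1] <- cnt[g1[i] + 1, g2[i] + 1] + 1
  # unambiguous haplotype counts (allele 1 = minor); order: 11, 10, 01, 00
  c11 <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
  c10 <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]
  c01 <- 2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2]
  c00 <- 2 * cnt[1, 1] + cnt[2, 1] + cnt[1, 2]
  ndh <- cnt[2, 2]
  tot <- 2 * n
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  iter <- 0
  repeat {
    iter <- iter + 1
    coup <- h[1] * h[4]
    rep_ <- h[2] * h[3]
    frac <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    newh <- c(c11 + ndh * frac, c10 + ndh * (1 - frac),
              c01 + ndh * (1 - frac), c00 + ndh * frac) / tot
    delta <- max(abs(newh - h))
    h <- newh
    if (delta < tol || iter >= max_iter) break
  }
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  D <- h[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax > 0) abs(D) / dmax else 0
  rr <- D / sqrt(pA * (1 - pA) * pB * (1 - pB))
  # multinomial log-likelihood of the genotype table under random mating
  gprob <- function(ph) {
    m <- matrix(0, 3, 3)
    hap <- matrix(c(ph[1], ph[2], ph[3], ph[4]), 2, 2,
                  dimnames = NULL)  # [allele1+1 backwards]; use direct sums
    # genotype (i,j) prob = sum over ordered haplotype pairs consistent
    p11 <- ph[1]; p10 <- ph[2]; p01 <- ph[3]; p00 <- ph[4]
    m[3, 3] <- p11^2; m[3, 2] <- 2 * p11 * p10; m[3, 1] <- p10^2
    m[2, 3] <- 2 * p11 * p01; m[2, 2] <- 2 * (p11 * p00 + p10 * p01)
    m[2, 1] <- 2 * p10 * p00
    m[1, 3] <- p01^2; m[1, 2] <- 2 * p01 * p00; m[1, 1] <- p00^2
    m
  }
  pm <- gprob(h)
  ll <- sum(ifelse(cnt > 0, cnt * log(pmax(pm, 1e-300)), 0))
  structure(list(
    hap = stats::setNames(h, c("p11", "p10", "p01", "p00")),
    D = D, Dprime = dprime, r = rr, iter = iter, loglik = ll, n = n
  ), class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("LD: D = %.4f, D' = %.3f, r = %.3f (n = %d, %d EM iterations)\n",
              x$D, x$Dprime, x$r, x$n, x$iter))
  invisible(x)
}

#' Combined two-SNP genotype grouping
#'
#' Assigns each patient to one of three groups: `snp1_hom_minor` when the
#' first SNP is the minor homozygote (regardless of the second SNP),
#' otherwise `snp2_hom_minor` when the second SNP is the minor homozygote,
#' otherwise `baseline` (at least one major allele at each SNP).  A
#' missing call at a deciding SNP yields `unassigned`.
#'
#' @param gm a [genotype_matrix()].
#' @param snp1_id,snp2_id the two SNPs (first takes precedence).
#' @return Factor of labels, one per patient, levels `baseline`,
#'   `snp2_hom_minor`, `snp1_hom_minor`, `unassigned`.
#' @export
two_snp_groups <- function(gm, snp1_id, snp2_id) {
  g1 <- encode(gm, snp1_id, "additive")
  g2 <- encode(gm, snp2_id, "additive")
  lab <- rep("unassigned", length(g1))
  lab[!is.na(g1) & g1 == 2] <- "snp1_hom_minor"
  undecided <- is.na(g1) | g1 < 2
  lab[undecided & !is.na(g2) & g2 == 2 & !is.na(g1)] <- "snp2_hom_minor"
  lab[!is.na(g1) & g1 < 2 & !is.na(g2) & g2 < 2] <- "baseline"
  factor(lab, levels = c("baseline", "snp2_hom_minor", "snp1_hom_minor",
                         "unassigned"))
}

#' Survival analysis of the combined two-SNP groups
#'
#' Cox model with indicators for the two non-baseline groups (baseline as
#' reference) plus covariates, Kaplan-Meier curves per group, and the
#' log-rank test across the three groups.  Supports cohort-stratified
#' pooled analyses via `strata`.
#'
#' @param labels factor from [two_snp_groups()], aligned with
#'   `clinical` rows.
#' @param clinical clinical table.
#' @param covariates covariate column names.
#' @param endpoint `"pfs"` or `"os"`.
#' @param strata optional clinical column of baseline-hazard strata.
#' @return List with `cox` (data.frame of per-group HR, CI, p, flags),
#'   `km` (list of `survival_curve`s), `logrank`, `n_groups`.
#' @export
combined_group_association <- function(labels, clinical,
                                       covariates = character(0),
                                       endpoint = c("pfs", "os"),
                                       strata = NULL) {
  endpoint <- match.arg(endpoint)
  time <- clinical[[paste0(endpoint, "_time")]]
  event <- clinical[[paste0(endpoint, "_event")]]
  use <- labels != "unassigned" & !is.na(time) & !is.na(event)
  lab <- droplevels(factor(labels[use],
                           levels = c("baseline", "snp2_hom_minor",
                                      "snp1_hom_minor")))
  if (!"baseline" %in% levels(lab) || sum(lab == "baseline") == 0) {
    stop("baseline group is empty", call. = FALSE)
  }
  cl <- clinical[use, , drop = FALSE]
  time <- time[use]; event <- event[use]
  n_groups <- table(lab)
  terms <- c("snp2_hom_minor", "snp1_hom_minor")
  present <- terms[terms %in% levels(lab) & table(lab)[terms] > 0]
  ind <- sapply(present, function(g) as.numeric(lab == g))
  ind <- matrix(ind, ncol = length(present),
                dimnames = list(NULL, present))
  covX <- NULL
  if (length(covariates)) {
    covX <- stats::model.matrix(
      ~., data = cl[, covariates, drop = FALSE]
    )[, -1, drop = FALSE]
  }
  str_vec <- if (!is.null(strata)) factor(cl[[strata]]) else NULL
  cox_tab <- data.frame(term = terms, hr = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_,
                        inestimable = TRUE, stringsAsFactors = FALSE)
  if (length(present)) {
    X <- cbind(ind, covX)
    fit <- tryCatch(cox_fit(X, time, event, strata = str_vec),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      for (g in present) {
        i <- match(g, names(fit$coef))
        row <- match(g, cox_tab$term)
        cox_tab$hr[row] <- fit$hr[i]
        cox_tab$ci_lower[row] <- fit$ci[i, 1]
        cox_tab$ci_upper[row] <- fit$ci[i, 2]
        cox_tab$p[row] <- fit$p[i]
        cox_tab$inestimable[row] <- FALSE
      }
    }
  }
  kms <- lapply(stats::setNames(levels(lab), levels(lab)), function(g) {
    km(time[lab == g], event[lab == g])
  })
  lr <- if (nlevels(lab) >= 2) logrank(time, event, lab) else NULL
  list(cox = cox_tab, km = kms, logrank = lr, n_groups = n_groups)
}

#' Compare a SNP's genotype distribution between two cohorts
#'
#' Fisher's exact test (full enumeration) on the genotype-count table of
#' one SNP in two genotype matrices; genotype classes absent from both
#' cohorts are dropped.
#'
#' @param gm1,gm2 two [genotype_matrix()]es sharing the SNP.
#' @param snp_id SNP id.
#' @return The exact p-value.
#' @export
genotype_distribution_test <- function(gm1, gm2, snp_id) {
  counts <- function(gm) {
    g <- encode(gm, snp_id, "additive")
    c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
      sum(g == 2, na.rm = TRUE))
  }
  tab <- cbind(counts(gm1), counts(gm2))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2) return(1)
  fisher_exact_rxc(tab)
}
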