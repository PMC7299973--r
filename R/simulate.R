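#' SNP specification for the cohort simulator
#'
#' @param snp_id unique SNP identifier.
#' @param maf minor-allele frequency in `[0, 0.5]`.
#' @param gene gene symbol (used by annotation-based filters).
#' @param ld_block optional LD-block id; block members are generated from
#'   a shared haplotype pool instead of independent allele draws.
#' @return A one-row data.frame; rbind rows to build a spec table.
#' @export
snp_spec <- function(snp_id, maf, gene = NA_character_,
                     ld_block = NA_character_) {
  if (maf < 0 || maf > 0.5) {
    stop("maf must lie in [0, 0.5]", call. = FALSE)
  }
  data.frame(snp_id = snp_id, maf = maf, gene = gene, ld_block = ld_block,
             stringsAsFactors = FALSE)
}

#' LD-block specification
#'
#' A haplotype pool over the block's member SNPs.  Haplotype frequencies
#' must sum to 1, and each member SNP's implied marginal frequency must
#' match its [snp_spec()] `maf` (checked at generation time).
#'
#' @param block_id block identifier.
#' @param members ordered member SNP ids.
#' @param haplotypes 0/1 matrix, one row per haplotype, one column per
#'   member.
#' @param freq haplotype frequencies, summing to 1.
#' @return An `ld_block_spec` list.
#' @export
ld_block_spec <- function(block_id, members, haplotypes, freq) {
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != length(members)) {
    stop("haplotypes must have one column per member SNP", call. = FALSE)
  }
  if (nrow(haplotypes) != length(freq)) {
    stop("one frequency per haplotype required", call. = FALSE)
  }
  if (abs(sum(freq) - 1) > 1e-9) {
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  }
  if (!all(haplotypes %in% c(0, 1))) {
    stop("haplotypes must be 0/1 vectors", call. = FALSE)
  }
  structure(list(block_id = block_id, members = members,
                 haplotypes = haplotypes, freq = freq),
            class = "ld_block_spec")
}

#' Planted SNP effect on survival
#'
#' @param snp_id SNP carrying the effect.
#' @param genetic_model `"additive"`, `"dominant"` or `"recessive"`.
#' @param log_hazard_ratio effect size on the log-hazard scale (per
#'   encoding unit).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(snp_id,
                        genetic_model = c("additive", "dominant",
                                          "recessive"),
                        log_hazard_ratio) {
  genetic_model <- match.arg(genetic_model)
  structure(list(snp_id = snp_id, genetic_model = genetic_model,
                 log_hazard_ratio = log_hazard_ratio),
            class = "effect_spec")
}

#' Survival-generator configuration
#'
#' Exponential baseline hazards with independent exponential censoring
#' and administrative censoring, in days.  Defaults emulate a metastatic
#' colorectal cancer cohort on first-line therapy: median PFS around 10
#' months and median OS around 2 years at a null linear predictor, light
#' random censoring, 5-6 years of administrative follow-up.  A Weibull
#' event-time option is available through `shape` (1 = exponential).
#'
#' @param baseline_hazard PFS event rate per day at zero linear
#'   predictor.
#' @param censoring_rate rate of the independent exponential censoring
#'   time for PFS.
#' @param admin_censor_time administrative censoring horizon (days).
#' @param covariate_effects named list of covariate log hazard ratios:
#'   a scalar for a numeric covariate (per unit), a named vector over
#'   non-reference levels for a factor.
#' @param os_baseline_hazard rate of the residual (post-progression)
#'   exponential added to the PFS event time to form the OS event time.
#' @param os_censoring_rate,os_admin_censor_time censoring of OS.
#' @param shape Weibull shape for the PFS event time (1 = exponential).
#' @param seed integer seed used by [simulate_survival()].
#' @return A `survival_gen_config` list.
#' @export
survival_gen_config <- function(baseline_hazard = log(2) / 300,
                                censoring_rate = log(2) / 1200,
                                admin_censor_time = 1825,
                                covariate_effects = list(),
                                os_baseline_hazard = log(2) / 420,
                                os_censoring_rate = log(2) / 2400,
                                os_admin_censor_time = 2190,
                                shape = 1,
                                seed = 1L) {
  stopifnot(baseline_hazard > 0, censoring_rate > 0, admin_censor_time > 0,
            os_baseline_hazard > 0, os_censoring_rate > 0,
            os_admin_censor_time > 0, shape > 0)
  structure(list(baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 admin_censor_time = admin_censor_time,
                 covariate_effects = covariate_effects,
                 os_baseline_hazard = os_baseline_hazard,
                 os_censoring_rate = os_censoring_rate,
                 os_admin_censor_time = os_admin_censor_time,
                 shape = shape, seed = as.integer(seed)),
            class = "survival_gen_config")
}

#' Simulate a genotype matrix
#'
#' SNPs outside LD blocks are drawn as two independent allele draws per
#' patient (Hardy-Weinberg proportions in expectation); SNPs inside a
#' block are drawn as two haplotypes from the block's pool.  Missing
#' calls are then planted completely at random at `missing_rate`.  Fully
#' reproducible from `seed`.
#'
#' @param n_patients cohort size.
#' @param snp_specs data.frame of [snp_spec()] rows.
#' @param ld_blocks list of [ld_block_spec()]s.
#' @param missing_rate per-entry missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_patients, snp_specs, ld_blocks = list(),
                               missing_rate = 0, seed = 1L) {
  stopifnot(n_patients >= 1, missing_rate >= 0, missing_rate < 1)
  snp_specs <- as.data.frame(snp_specs)
  if (anyDuplicated(snp_specs$snp_id)) {
    stop("duplicate snp_id in snp_specs", call. = FALSE)
  }
  if (any(snp_specs$maf < 0 | snp_specs$maf > 0.5)) {
    stop("maf must lie in [0, 0.5]", call. = FALSE)
  }
  P <- nrow(snp_specs)
  blocked <- character(0)
  for (bl in ld_blocks) {
    marg <- drop(bl$freq %*% bl$haplotypes)
    spec_maf <- snp_specs$maf[match(bl$members, snp_specs$snp_id)]
    if (anyNA(spec_maf)) {
      stop("block member missing from snp_specs: ",
           paste(setdiff(bl$members, snp_specs$snp_id), collapse = ", "),
           call. = FALSE)
    }
    if (any(abs(marg - spec_maf) > 1e-6)) {
      stop(sprintf("block %s: haplotype pool marginal frequencies disagree with snp_specs maf",
                   bl$block_id), call. = FALSE)
    }
    blocked <- c(blocked, bl$members)
  }
  if (anyDuplicated(blocked)) {
    stop("a SNP belongs to more than one LD block", call. = FALSE)
  }
  codes <- withr::with_seed(as.integer(seed), {
    out <- matrix(NA_integer_, n_patients, P)
    free <- !(snp_specs$snp_id %in% blocked)
    for (j in which(free)) {
      out[, j] <- stats::rbinom(n_patients, 2, snp_specs$maf[j])
    }
    for (bl in ld_blocks) {
      cols <- match(bl$members, snp_specs$snp_id)
      h1 <- sample.int(nrow(bl$haplotypes), n_patients, replace = TRUE,
                       prob = bl$freq)
      h2 <- sample.int(nrow(bl$haplotypes), n_patients, replace = TRUE,
                       prob = bl$freq)
      out[, cols] <- bl$haplotypes[h1, , drop = FALSE] +
        bl$haplotypes[h2, , drop = FALSE]
    }
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(n_patients * P) < missing_rate,
                     n_patients, P)
      out[mask] <- NA_integer_
    }
    out
  })
  snps <- data.frame(
    snp_id = snp_specs$snp_id, chrom = "1",
    pos = seq_len(P) * 1000L, ref = "A", alt = "B", minor = "B",
    gene = if ("gene" %in% names(snp_specs)) snp_specs$gene
           else NA_character_,
    stringsAsFactors = FALSE
  )
  genotype_matrix(codes, snps, sprintf("P%04d", seq_len(n_patients)))
}

#' Plant missing calls into a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param missing_rate per-entry missingness probability.
#' @param seed integer seed.
#' @return The matrix with missing calls added completely at random.
#' @export
gm_add_missing <- function(gm, missing_rate, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (missing_rate == 0) return(gm)
  withr::with_seed(as.integer(seed), {
    mask <- matrix(stats::runif(length(gm$codes)) < missing_rate,
                   nrow(gm$codes), ncol(gm$codes))
    gm$codes[mask] <- NA_integer_
  })
  gm
}

# linear predictor from planted SNP effects + covariate effects
survival_linpred <- function(gm, clinical_covariates, effects, config) {
  n <- nrow(gm$codes)
  lp <- numeric(n)
  for (ef in effects) {
    if (!ef$snp_id %in% gm$snps$snp_id) {
      stop("effect SNP not in genotype matrix: ", ef$snp_id, call. = FALSE)
    }
    x <- encode(gm, ef$snp_id, ef$genetic_model)
    x[is.na(x)] <- 0  # reference contribution for missing calls
    lp <- lp + ef$log_hazard_ratio * x
  }
  for (nm in names(config$covariate_effects)) {
    if (!nm %in% names(clinical_covariates)) {
      stop("unknown covariate in covariate_effects: ", nm, call. = FALSE)
    }
    eff <- config$covariate_effects[[nm]]
    v <- clinical_covariates[[nm]]
    if (is.numeric(v)) {
      lp <- lp + eff * v
    } else {
      v <- as.character(v)
      add <- eff[v]
      add[is.na(add)] <- 0  # reference level
      lp <- lp + unname(add)
    }
  }
  lp
}

#' Simulate right-censored PFS and OS outcomes
#'
#' PFS event times are Weibull (exponential by default) with rate
#' `baseline_hazard * exp(linear predictor)`; censoring is the minimum of
#' an independent exponential draw and the administrative horizon.  The
#' OS event time is the PFS event time plus an independent exponential
#' residual whose rate is `os_baseline_hazard * exp(SNP effects)`, so
#' OS >= PFS by construction; OS has its own censoring.
#'
#' @param gm a [genotype_matrix()] (ideally before missingness is
#'   planted; missing codes contribute the reference-genotype effect).
#' @param clinical_covariates data.frame of covariates, rows aligned with
#'   `gm` patients.
#' @param effects list of [effect_spec()]s.
#' @param config a [survival_gen_config()].
#' @return data.frame with `pfs_time`, `pfs_event`, `os_time`,
#'   `os_event` (days, 0/1).
#' @export
simulate_survival <- function(gm, clinical_covariates, effects, config) {
  n <- nrow(gm$codes)
  lp <- survival_linpred(gm, clinical_covariates, effects, config)
  lp_snp <- survival_linpred(
    gm, clinical_covariates, effects,
    survival_gen_config(covariate_effects = list())
  )
  withr::with_seed(config$seed, {
    rate <- config$baseline_hazard * exp(lp)
    u <- stats::runif(n)
    t_ev <- if (config$shape == 1) {
      -log(u) / rate
    } else {
      (-log(u) / rate)^(1 / config$shape)
    }
    t_cens <- pmin(stats::rexp(n, config$censoring_rate),
                   config$admin_censor_time)
    pfs_time <- pmin(t_ev, t_cens)
    pfs_event <- as.integer(t_ev <= t_cens)
    resid <- stats::rexp(n, config$os_baseline_hazard * exp(lp_snp))
    t_os <- t_ev + resid
    c_os <- pmin(stats::rexp(n, config$os_censoring_rate),
                 config$os_admin_censor_time)
    os_time <- pmin(t_os, c_os)
    os_event <- as.integer(t_os <= c_os)
    data.frame(pfs_time = pfs_time, pfs_event = pfs_event,
               os_time = os_time, os_event = os_event)
  })
}

#' Simulate clinical covariates
#'
#' Sex, age and KRAS status with marginals resembling a metastatic
#' colorectal cancer trial population (60/40 sex split, age centred near
#' 63, roughly half KRAS wild-type with a sixth unknown).
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @return data.frame with columns `sex`, `age`, `kras`.
#' @export
simulate_covariates <- function(n, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    data.frame(
      sex = factor(sample(c("male", "female"), n, TRUE, c(0.6, 0.4)),
                   levels = c("male", "female")),
      age = round(stats::rnorm(n, 63, 10), 1),
      kras = factor(sample(c("wt", "mutant", "unknown"), n, TRUE,
                           c(0.48, 0.34, 0.18)),
                    levels = c("wt", "mutant", "unknown"))
    )
  })
}

#' Simulate a complete cohort
#'
#' Generates genotypes (complete), covariates and survival outcomes, then
#' plants missing genotype calls.  Component seeds are derived from the
#' master seed with fixed offsets (genotypes +1, covariates +2,
#' survival +3, missingness +4).
#'
#' @param n_patients cohort size.
#' @param snp_specs,ld_blocks,effects,config as in [simulate_genotypes()]
#'   and [simulate_survival()].
#' @param missing_rate genotype missingness rate.
#' @param seed master seed.
#' @param cohort cohort label recorded in the clinical table.
#' @return List with `gm` (genotype matrix, with missingness) and
#'   `clinical` (covariates + endpoints + cohort label).
#' @export
simulate_cohort <- function(n_patients, snp_specs, ld_blocks = list(),
                            effects = list(), config = survival_gen_config(),
                            missing_rate = 0, seed = 1L, cohort = "SIM") {
  seed <- as.integer(seed)
  gm_full <- simulate_genotypes(n_patients, snp_specs, ld_blocks,
                                missing_rate = 0, seed = seed + 1L)
  covs <- simulate_covariates(n_patients, seed = seed + 2L)
  config$seed <- seed + 3L
  outcomes <- simulate_survival(gm_full, covs, effects, config)
  gm <- gm_add_missing(gm_full, missing_rate, seed = seed + 4L)
  clinical <- cbind(
    data.frame(patient_id = gm$patient_ids, stringsAsFactors = FALSE),
    covs, outcomes,
    data.frame(cohort = cohort, stringsAsFactors = FALSE)
  )
  list(gm = gm, clinical = clinical)
}

#' Cohort-characteristics contingency tables
#'
#' The printed patient-characteristic count tables comparing the
#' discovery cohort (APD) with the two validation cohorts (MAVERICC,
#' TRIBE), used as fixtures for the contingency tests: chemotherapy
#' backbone, KRAS status (including the unknown row), primary tumour side
#' (excluding unknown), BRAF status (excluding unknown), adjuvant
#' chemotherapy, sex and age.
#'
#' @param name one of `"backbone"`, `"kras_with_unknown"`,
#'   `"site_excl_unknown"`, `"braf_excl_unknown"`, `"adjuvant"`, `"sex"`,
#'   `"age_excl_unknown"`; `NULL` returns the full named list.
#' @return A labelled integer matrix, or the list of all tables.
#' @export
table1_fixtures <- function(name = NULL) {
  tabs <- list(
    backbone = matrix(
      c(177, 163, 215, 3, 0, 0), nrow = 2, byrow = TRUE,
      dimnames = list(c("FP-based", "Non-FP"),
                      c("APD", "MAVERICC", "TRIBE"))),
    kras_with_unknown = matrix(
      c(87, 87, 88, 60, 56, 90, 33, 20, 37), nrow = 3, byrow = TRUE,
      dimnames = list(c("wt", "mutant", "unknown"),
                      c("APD", "MAVERICC", "TRIBE"))),
    site_excl_unknown = matrix(
      c(67, 53, 96, 147), nrow = 2, byrow = TRUE,
      dimnames = list(c("right", "left"), c("MAVERICC", "TRIBE"))),
    braf_excl_unknown = matrix(
      c(153, 168, 18, 10), nrow = 2, byrow = TRUE,
      dimnames = list(c("wt", "mutant"), c("APD", "TRIBE"))),
    adjuvant = matrix(
      c(143, 188, 20, 27), nrow = 2, byrow = TRUE,
      dimnames = list(c("no", "yes"), c("MAVERICC", "TRIBE"))),
    sex = matrix(
      c(108, 103, 132, 72, 60, 83), nrow = 2, byrow = TRUE,
      dimnames = list(c("male", "female"),
                      c("APD", "MAVERICC", "TRIBE"))),
    age_excl_unknown = matrix(
      c(77, 101, 156, 99, 62, 59), nrow = 2, byrow = TRUE,
      dimnames = list(c("le65", "gt65"),
                      c("APD", "MAVERICC", "TRIBE")))
  )
  if (is.null(name)) return(tabs)
  if (!name %in% names(tabs)) {
    stop("unknown table: ", name, call. = FALSE)
  }
  tabs[[name]]
}
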