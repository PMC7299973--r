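#' Cohort covariate presets for adjusted Cox models
#'
#' The covariate sets used for adjustment in each cohort's Cox models:
#' the discovery cohort adjusts for sex, age, grade of differentiation,
#' chemotherapy line, chemotherapy backbone and BRAF status; the first
#' validation cohort for age, ECOG performance status, number of
#' metastases and resection of the primary tumour; the second validation
#' cohort for age, sex, ECOG, primary tumour site, resection,
#' liver-limited disease, adjuvant chemotherapy, BRAF and RAS status.
#' `pooled` is the intersection used in cohort-stratified combined
#' analyses.
#'
#' @param cohort preset name; `NULL` lists all presets.
#' @return Character vector of clinical column names.
#' @export
covariate_presets <- function(cohort = NULL) {
  presets <- list(
    discovery = c("sex", "age", "grade", "chemo_line", "backbone", "braf"),
    validation1 = c("age", "ecog", "n_metastases", "resection"),
    validation2 = c("age", "sex", "ecog", "site", "resection",
                    "liver_limited", "adjuvant", "braf", "ras"),
    pooled = "age",
    simulated = c("sex", "age")
  )
  if (is.null(cohort)) return(presets)
  if (!cohort %in% names(presets)) {
    stop("unknown covariate preset: ", cohort, call. = FALSE)
  }
  presets[[cohort]]
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  config
}

config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

# in-memory objects in a config (genotype matrices, clinical tables) are
# recorded in the manifest by shape, not content
manifest_safe <- function(config) {
  lapply(config, function(x) {
    if (inherits(x, "genotype_matrix")) {
      sprintf("<genotype_matrix %d x %d>", nrow(x$codes), ncol(x$codes))
    } else if (is.data.frame(x)) {
      sprintf("<data.frame %d x %d>", nrow(x), ncol(x))
    } else if (is.list(x)) {
      manifest_safe(x)
    } else {
      x
    }
  })
}

write_manifest <- function(out_dir, stage, config, extra = list()) {
  config <- manifest_safe(config)
  manifest <- c(list(stage = stage, config = config,
                     config_md5 = config_digest(config)), extra)
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Simulate a cohort from a config and write its files
#'
#' Validates the simulation config, generates the cohort with
#' [simulate_cohort()], and writes `genotypes.vcf`, `clinical.tsv`, the
#' ground-truth `effects.json` and a run manifest to `out_dir`.  The
#' config (list or YAML path) needs `n_patients`, `snps` (rows with
#' `snp_id`, `maf`, optional `gene`), and optionally `effects` (rows with
#' `snp_id`, `genetic_model`, `log_hazard_ratio`), `missing_rate`,
#' `seed`, `cohort`, and `survival` overrides for
#' [survival_gen_config()].
#'
#' @param config list or YAML path.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the cohort and the file paths.
#' @export
pipeline_simulate <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  if (is.null(config$n_patients) || is.null(config$snps)) {
    stop("config needs n_patients and snps", call. = FALSE)
  }
  snps <- do.call(rbind, lapply(config$snps, function(s) {
    snp_spec(s$snp_id, s$maf, gene = s$gene %||% NA_character_)
  }))
  effects <- lapply(config$effects %||% list(), function(e) {
    effect_spec(e$snp_id, e$genetic_model, e$log_hazard_ratio)
  })
  surv_cfg <- do.call(survival_gen_config, config$survival %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(
    config$n_patients, snps, effects = effects, config = surv_cfg,
    missing_rate = config$missing_rate %||% 0,
    seed = config$seed %||% 1L, cohort = config$cohort %||% "SIM"
  )
  vcf <- file.path(out_dir, "genotypes.vcf")
  tsv <- file.path(out_dir, "clinical.tsv")
  eff <- file.path(out_dir, "effects.json")
  write_vcf(cohort$gm, vcf)
  write_clinical(cohort$clinical, tsv)
  jsonlite::write_json(config$effects %||% list(), eff, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_manifest(out_dir, "simulate", config)
  invisible(list(gm = cohort$gm, clinical = cohort$clinical,
                 paths = c(vcf = vcf, clinical = tsv, effects = eff)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the discovery stage: QC, stability selection, candidate scan
#'
#' Reads the discovery cohort, applies the discovery QC filter, runs
#' LASSO (alpha = 1) and elastic-net (alpha = 0.5) stability selection,
#' aggregates candidates with the two frequency thresholds, removes
#' Hardy-Weinberg failures, and scans the surviving candidates with
#' covariate-adjusted Cox models.  Writes selection profiles, the
#' candidate list, the association table and a manifest to `out_dir`.
#'
#' Config fields: `vcf`, `clinical` (paths; or pass `gm`/`clinical`
#' objects directly), `ref_maf` path or named vector, `gene_map` path or
#' `NULL` (use the matrix's own annotations), `covariates`, `n_repeats`,
#' `subsample`, `k`, `th_lasso`, `th_en`, `master_seed`, `n_lambda`.
#'
#' @param config list or YAML path.
#' @param out_dir output directory.
#' @return Invisibly, a list with the QC report, both profiles, the
#'   candidate set and the association table.
#' @export
pipeline_discover <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gm <- if (!is.null(config$gm)) config$gm else read_vcf(config$vcf)
  clinical <- if (is.data.frame(config$clinical)) config$clinical
              else read_clinical(config$clinical)
  ref_maf <- if (is.character(config$ref_maf)) read_maf_table(config$ref_maf)
             else config$ref_maf
  gene_map <- if (is.character(config$gene_map)) read_gene_map(config$gene_map)
              else config$gene_map

  qc <- discovery_filter(gm, ref_maf, gene_map)
  kept <- attr(qc, "kept")
  if (!length(kept)) stop("discovery QC kept no SNPs", call. = FALSE)
  gm_qc <- gm_subset(gm, snps = kept)

  seed <- as.integer(config$master_seed %||% 1L)
  n_repeats <- config$n_repeats %||% 1000
  args <- list(gm = gm_qc, clinical = clinical,
               n_repeats = n_repeats,
               subsample = config$subsample %||% 0.9,
               k = config$k %||% 3,
               n_lambda = config$n_lambda %||% 50)
  prof_lasso <- do.call(run_stability, c(args, list(
    alpha = 1, master_seed = seed)))
  prof_en <- do.call(run_stability, c(args, list(
    alpha = 0.5, master_seed = seed + 2L * n_repeats + 1L)))

  cand <- candidate_set(prof_lasso, prof_en,
                        th_lasso = config$th_lasso %||% 0.25,
                        th_en = config$th_en %||% 0.70)
  cand_hwe <- post_hwe_filter(cand, gm_qc)
  assoc <- if (length(cand_hwe)) {
    adjusted_scan(cand_hwe, gm_qc, clinical,
                  covariates = config$covariates %||% character(0),
                  endpoint = "pfs")
  } else {
    NULL
  }

  prof_tsv <- function(p, tag) {
    df <- data.frame(snp_id = names(p$count), count = as.integer(p$count),
                     frequency = p$frequency, algorithm = tag)
    df
  }
  profiles <- rbind(prof_tsv(prof_lasso, "lasso"), prof_tsv(prof_en, "en"))
  utils::write.table(profiles, file.path(out_dir, "selection_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(snp_id = as.character(cand_hwe)),
    file.path(out_dir, "candidates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(assoc)) {
    utils::write.table(assoc, file.path(out_dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_qc_report(qc, file.path(out_dir, "qc_report.tsv"))
  write_manifest(out_dir, "discover", config, extra = list(
    n_snps_input = ncol(gm$codes), n_snps_qc = length(kept),
    n_candidates_raw = length(cand), n_candidates = length(cand_hwe),
    hwe_dropped = attr(cand_hwe, "dropped"),
    mean_set_size_lasso = prof_lasso$mean_size,
    mean_set_size_en = prof_en$mean_size
  ))
  invisible(list(qc = qc, profile_lasso = prof_lasso, profile_en = prof_en,
                 candidates = cand_hwe, associations = assoc))
}

#' Run the validation stage on an independent cohort
#'
#' Applies the validation coverage filter, reports candidates not
#' accessible in the validation genotypes, checks Hardy-Weinberg
#' equilibrium, compares genotype distributions against the discovery
#' cohort (Fisher's exact test), runs the covariate-adjusted association
#' scan (optionally within subgroups), and analyses specified two-SNP
#' combinations.  Writes TSV outputs and a manifest.
#'
#' Config fields: `vcf`/`clinical` (validation cohort, paths or
#' objects), `discovery_vcf` or `discovery_gm` (for distribution tests),
#' `covariates`, `min_call_rate`, `subgroup` (named list), `snp_pairs`
#' (list of two-id vectors).
#'
#' @param config list or YAML path.
#' @param candidates candidate SNP ids from discovery.
#' @param out_dir output directory.
#' @return Invisibly, a list with accessibility, HWE and distribution
#'   tables, the association scan and combination analyses.
#' @export
pipeline_validate <- function(config, candidates, out_dir) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gm <- if (!is.null(config$gm)) config$gm else read_vcf(config$vcf)
  clinical <- if (is.data.frame(config$clinical)) config$clinical
              else read_clinical(config$clinical)
  gm_disc <- if (!is.null(config$discovery_gm)) config$discovery_gm
             else if (!is.null(config$discovery_vcf))
               read_vcf(config$discovery_vcf)
             else NULL

  covered <- validation_filter(gm, config$min_call_rate %||% 0.80)
  accessible <- intersect(candidates, covered)
  not_accessible <- setdiff(candidates, accessible)
  access <- data.frame(
    snp_id = candidates,
    accessible = candidates %in% accessible
  )
  result <- list(accessible = access)
  if (length(accessible)) {
    gm_acc <- gm_subset(gm, snps = accessible)
    hwe <- data.frame(snp_id = accessible, hwe_p = gm_hwe(gm_acc))
    dist <- if (!is.null(gm_disc)) {
      data.frame(
        snp_id = accessible,
        fisher_p = vapply(accessible, function(s) {
          genotype_distribution_test(gm_disc, gm, s)
        }, numeric(1))
      )
    } else NULL
    assoc <- adjusted_scan(accessible, gm, clinical,
                           covariates = config$covariates %||% character(0),
                           endpoint = "pfs",
                           subgroup = config$subgroup %||% NULL)
    result$hwe <- hwe
    result$distribution <- dist
    result$associations <- assoc
    utils::write.table(hwe, file.path(out_dir, "validation_hwe.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(dist)) {
      utils::write.table(dist,
                         file.path(out_dir, "genotype_distribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(assoc,
                       file.path(out_dir, "validation_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  combos <- lapply(config$snp_pairs %||% list(), function(pair) {
    labels <- two_snp_groups(gm, pair[[1]], pair[[2]])
    idx <- match(gm$patient_ids, clinical$patient_id)
    combined_group_association(labels, clinical[idx, , drop = FALSE],
                               covariates = config$covariates %||%
                                 character(0),
                               endpoint = "pfs")
  })
  result$combinations <- combos
  utils::write.table(access, file.path(out_dir, "accessibility.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "validate", config, extra = list(
    n_candidates = length(candidates),
    n_accessible = length(accessible),
    not_accessible = not_accessible
  ))
  invisible(result)
}
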