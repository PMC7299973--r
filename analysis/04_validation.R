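#!/usr/bin/env Rscript
# Stage 4: candidate validation in the two independent cohorts —
# coverage filter, Hardy-Weinberg check, genotype-distribution
# comparison against discovery (Fisher), and covariate-adjusted
# association scans (overall and KRAS wild-type subgroup).
source("analysis/00_config.R")

cand_file <- file.path(RESULTS, "discovery", "candidates.tsv")
if (!file.exists(cand_file)) stop("run analysis/03_discovery.R first")
candidates <- read.delim(cand_file)$snp_id
gm_disc <- read_vcf(file.path(COHORT_DIR, "discovery.vcf"))

for (nm in c("validation1", "validation2")) {
  gm <- read_vcf(file.path(COHORT_DIR, paste0(nm, ".vcf")))
  clinical <- read_clinical(file.path(COHORT_DIR, paste0(nm, ".tsv")))
  out <- file.path(RESULTS, nm)
  res <- pipeline_validate(list(
    gm = gm, clinical = clinical, discovery_gm = gm_disc,
    covariates = DISCOVERY_COVARIATES
  ), candidates, out)
  n_acc <- sum(res$accessible$accessible)
  cat(sprintf("%s: %d of %d candidates accessible (>= 80%% coverage)\n",
              nm, n_acc, length(candidates)))
  if (!is.null(res$distribution)) {
    ndiff <- sum(res$distribution$fisher_p < 0.05)
    cat(sprintf("  genotype distribution differs from discovery for %d SNPs (Fisher p < 0.05)\n",
                ndiff))
  }
  if (!is.null(res$associations)) {
    sig <- subset(res$associations, !inestimable & wald_p < 0.05)
    cat(sprintf("  nominally significant associations (any model): %d rows\n",
                nrow(sig)))
  }
  # KRAS wild-type subgroup scan
  wt <- adjusted_scan(intersect(candidates, gm$snps$snp_id), gm, clinical,
                      covariates = DISCOVERY_COVARIATES, endpoint = "pfs",
                      models = "dominant", subgroup = list(kras = "wt"))
  write.table(wt, file.path(out, "kras_wt_associations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  KRAS wild-type subgroup scan written (%d rows)\n",
              nrow(wt)))
}
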