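#!/usr/bin/env Rscript
# Stage 1: simulate a discovery cohort and two validation cohorts with a
# shared genetic architecture (two causal SNPs, one LD block), writing
# VCF + clinical TSV + ground-truth effects per cohort.
source("analysis/00_config.R")

dir.create(COHORT_DIR, recursive = TRUE, showWarnings = FALSE)
panel <- make_snp_panel()
blocks <- make_ld_blocks()
effects <- make_effects()

cohorts <- list(
  discovery   = list(n = 180, seed = MASTER_SEED + 1L, missing = 0.03),
  validation1 = list(n = 163, seed = MASTER_SEED + 2L, missing = 0.05),
  validation2 = list(n = 215, seed = MASTER_SEED + 3L, missing = 0.05)
)

for (nm in names(cohorts)) {
  cc <- cohorts[[nm]]
  coh <- simulate_cohort(cc$n, panel, ld_blocks = blocks,
                         effects = effects, missing_rate = cc$missing,
                         seed = cc$seed, cohort = nm)
  write_vcf(coh$gm, file.path(COHORT_DIR, paste0(nm, ".vcf")))
  write_clinical(coh$clinical, file.path(COHORT_DIR, paste0(nm, ".tsv")))
  ev <- mean(coh$clinical$pfs_event)
  cat(sprintf("%s: %d patients, %d SNPs, %.0f%% PFS events, median PFS %.0f days\n",
              nm, cc$n, ncol(coh$gm$codes), 100 * ev,
              km(coh$clinical$pfs_time, coh$clinical$pfs_event)$median))
}

# reference MAF table (the generating frequencies stand in for the
# population reference panel) and SNP -> gene map
write.table(data.frame(snp_id = panel$snp_id, maf = panel$maf),
            file.path(COHORT_DIR, "ref_maf.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(snp_id = panel$snp_id, gene = panel$gene),
            file.path(COHORT_DIR, "gene_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote cohort files under", COHORT_DIR, "\n")
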