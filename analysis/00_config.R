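# Shared settings for the analysis workflow.  Every script can be run
# from the repository root with:  Rscript analysis/<script>.R
library(snpstab)

RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohorts")
MASTER_SEED <- 20200617L

# SNP panel: 400 noise SNPs, two causal SNPs on different genes, and a
# two-SNP LD block tagging the first causal variant (D' = 1 by pool
# construction), echoing the structure seen in real discovery panels.
make_snp_panel <- function() {
  specs <- withr::with_seed(MASTER_SEED, {
    do.call(rbind, lapply(1:400, function(i) {
      snp_spec(sprintf("noise%03d", i), maf = runif(1, 0.05, 0.5),
               gene = sprintf("NG%03d", (i - 1) %/% 4 + 1))
    }))
  })
  rbind(
    snp_spec("causal_inflam", 0.35, gene = "INFLAM1"),
    snp_spec("tag_inflam", 0.30, gene = "INFLAM1"),
    snp_spec("causal_er", 0.25, gene = "ERGENE1"),
    specs
  )
}

make_ld_blocks <- function() {
  # haplotype pool over (causal_inflam, tag_inflam): the tag is carried
  # on a subset of causal haplotypes, D' = 1
  list(ld_block_spec(
    "inflam_block", c("causal_inflam", "tag_inflam"),
    rbind(c(1, 1), c(1, 0), c(0, 0)),
    c(0.30, 0.05, 0.65)
  ))
}

make_effects <- function() {
  list(
    effect_spec("causal_inflam", "dominant", log(2.2)),
    effect_spec("causal_er", "recessive", log(2.8))
  )
}

DISCOVERY_COVARIATES <- c("sex", "age")
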