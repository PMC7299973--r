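#!/usr/bin/env Rscript
# Stage 2: discovery-cohort SNP quality control — carrier frequency,
# reference MAF, call rate, unique gene annotation, Hardy-Weinberg.
source("analysis/00_config.R")

gm <- read_vcf(file.path(COHORT_DIR, "discovery.vcf"))
ref <- read_maf_table(file.path(COHORT_DIR, "ref_maf.tsv"))
gmap <- read_gene_map(file.path(COHORT_DIR, "gene_map.tsv"))

qc <- discovery_filter(gm, ref, gmap)
write_qc_report(qc, file.path(RESULTS, "qc_report.tsv"))

kept <- attr(qc, "kept")
cat(sprintf("QC: %d of %d SNPs kept\n", length(kept), nrow(qc)))
cat(sprintf("  carrier-frequency failures: %d\n",
            sum(!qc$carrier_freq_pass)))
cat(sprintf("  reference-MAF failures:     %d\n", sum(!qc$ref_maf_pass)))
cat(sprintf("  call-rate failures:         %d\n", sum(!qc$call_rate_pass)))
cat(sprintf("  gene-annotation failures:   %d\n",
            sum(!qc$unique_gene_pass)))
cat(sprintf("  HWE p <= 1e-4 (flagged):    %d\n", sum(qc$hwe_p <= 1e-4)))
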