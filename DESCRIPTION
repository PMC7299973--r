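Package: snpstab
Title: Germline SNP Survival Biomarker Discovery by Penalized Cox
    Stability Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for discovering and validating germline
    single-nucleotide polymorphism (SNP) biomarkers of survival outcomes in
    treated patient cohorts.  Implements SNP quality-control filters
    (call rate, carrier frequency, reference minor-allele frequency,
    Hardy-Weinberg exact test), an elastic-net penalized Cox proportional
    hazards solver by cyclic coordinate descent with cross-validation,
    stability selection over repeated patient subsamples,
    covariate-adjusted genotype association under codominant, dominant and
    recessive genetic models, permutation-corrected log-rank testing,
    pairwise linkage disequilibrium from unphased genotypes, two-SNP
    combined-genotype analysis, and model evaluation by inverse probability
    of censoring weighted Brier scores and bootstrapped prediction error
    curves.  Includes a synthetic-cohort generator producing
    Hardy-Weinberg genotypes with linkage-disequilibrium blocks and
    right-censored survival times with planted genetic effects.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    survival,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
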