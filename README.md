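# snpstab

Germline SNP biomarker discovery for survival outcomes by penalized Cox
stability selection — an end-to-end, tested reimplementation of the
discovery/validation workflow used in pharmacogenomic studies of
bevacizumab + chemotherapy response in metastatic colorectal cancer.

## The problem

A discovery cohort of a few hundred treated patients is genotyped at tens
of thousands of germline SNPs; the goal is to find the handful of variants
whose genotype is associated with progression-free survival (PFS), and to
confirm them in independent cohorts.  With P ≫ N, single-SNP testing
drowns in multiplicity and a single penalized fit overfits the particular
sample.  The workflow implemented here addresses both:

1. **QC filters** — carrier frequency ≥ 10% and < 100%, reference
   (population) minor-allele frequency ≥ 5%, call rate ≥ 90%, unique gene
   annotation; Hardy–Weinberg exact test (SNPs require p > 1e-4).
2. **Stability selection** — three-fold cross-validated Cox LASSO
   (α = 1) and elastic net (α = 0.5), each repeated over random 90%
   patient subsamples.  Each repeat keeps the SNPs with nonzero
   coefficients at λ_min (minimum mean cross-validated partial-likelihood
   deviance, Verweij–Van Houwelingen).  Candidates are SNPs selected in
   > 25% of LASSO repeats or ≥ 70% of elastic-net repeats.
3. **Association & validation** — covariate-adjusted Cox models under
   codominant / dominant / recessive genetic codings with across-genotype
   Wald tests; permutation-corrected log-rank tests; Fisher exact
   comparison of genotype distributions between cohorts; pairwise LD
   (D′, r) by EM from unphased genotypes; two-SNP combined-genotype
   groups with pooled cohort-stratified Cox models.
4. **Model evaluation** — inverse-probability-of-censoring-weighted
   (IPCW) Brier scores and bootstrapped out-of-bag prediction error
   curves comparing null, clinical, and clinical + SNP models.

The penalized Cox solver is written from scratch (cyclic coordinate
descent with soft-thresholding on the IRLS quadratic approximation of the
Breslow partial likelihood, sequential strong-rule screening, warm-started
regularization path, KKT audits), as is the Newton–Raphson Cox fitter
with Efron/Breslow ties used for reporting models.  Real patient data for
this kind of study sit under restricted access, so the package ships a
synthetic-cohort generator (Hardy–Weinberg genotypes, LD blocks from
haplotype pools, covariates, exponential proportional-hazards survival
with planted dominant/recessive/additive SNP effects and independent
censoring) that the entire workflow — and its test suite — runs on.

## The model

For patient *i* with covariates *x*, the hazard is
`h(t | x) = h0(t) exp(x'β)`.  The elastic-net estimate solves

```
min over β of  -(1/n) · Breslow log partial likelihood(β)
               + λ [ α ||β||₁ + (1-α)/2 ||β||₂² ]
```

over a decreasing λ path; selection frequency of each SNP across
subsample repeats is the stability score.  Genotypes enter the penalized
model as additive 0/1/2 minor-allele counts (mean-imputed); reporting
models use the coding named in the output (dominant = any minor allele,
recessive = minor homozygote, codominant = two indicators).

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
cohorts (discovery n = 180, validation n = 163 and n = 215, 403 SNPs
with two planted causal variants and one LD block):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc.R
Rscript analysis/03_discovery.R
Rscript analysis/04_validation.R
Rscript analysis/05_combination.R
Rscript analysis/06_prediction_error.R
```

Output of the discovery stage (200 stability repeats per algorithm):

```
LASSO profile: mean selected set 5.1 SNPs per repeat
Elastic net profile: mean selected set 6.9 SNPs per repeat
Candidates after thresholds + HWE: 8
[1] "causal_inflam" "noise052" "noise061" "noise065" ...
top elastic-net selection frequencies:
causal_inflam      noise300      noise061
        0.905         0.670         0.650
```

The planted dominant variant (`causal_inflam`, HR 2.2) tops the profile
at 0.905; a handful of noise SNPs cross the threshold at this cohort
size, which is exactly why the validation stage exists.  The combination
stage recovers the planted LD block (`D' = 1.000, r = 0.867`) and the
pooled two-SNP analysis gives

```
            term       hr ci_lower ci_upper        p
1 snp2_hom_minor 1.297    0.959    1.755    9.2e-02
2 snp1_hom_minor 2.873    1.968    4.193    4.5e-08
```

i.e. the recessive-coded causal SNP carries a strongly elevated hazard
against the both-major-allele baseline.  The prediction-error stage shows
the 2-SNP model improving on the clinical model (out-of-bag Brier 0.2375
vs 0.2575 at median follow-up) while 20 noise SNPs make it worse
(0.2933) — the overfitting signature the workflow is designed to catch.

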