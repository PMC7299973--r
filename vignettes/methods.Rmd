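---
title: "Methods: penalized Cox stability selection for germline SNP discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized Cox stability selection for germline SNP discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(snpstab)
```

## Overview

`snpstab` implements a discovery/validation workflow for germline SNP
biomarkers of right-censored survival endpoints in treated cancer
cohorts: quality control, repeated cross-validated penalized Cox
feature selection over patient subsamples, covariate-adjusted genotype
association under the three classical genetic models,
permutation-corrected log-rank testing, pairwise linkage disequilibrium,
two-SNP combined-genotype analysis, and model evaluation with IPCW Brier
scores.  This vignette records the modelling assumptions and the
numerical and design choices a maintainer would want to know.

## Genotype representation

Genotypes are minor-allele counts 0/1/2 with `NA` for missing calls;
alleles are oriented at load time so the counted allele has sample
frequency ≤ 0.5 (ties keep ALT).  "Dominant" and "recessive" are defined
with respect to the minor allele; analyses phrased against the *major*
allele (e.g. "any major-allele carrier") are expressed through the
`flip` argument of `encode()`, which exchanges allele roles before
encoding rather than inventing a second labelling convention.

## The penalized Cox solver

The elastic-net estimate minimizes
`-(1/n)·loglik_Breslow(β) + λ(α‖β‖₁ + (1-α)/2‖β‖₂²)` by cyclic
coordinate descent on the iteratively reweighted least-squares quadratic
approximation, with:

* predictors standardized internally to zero mean and unit *population*
  (1/N) variance; coefficients are reported on the original scale;
* Breslow tie handling inside the solver; the unpenalized
  Newton–Raphson fitter used for reporting models defaults to Efron
  (the two coincide exactly when no event times are tied, which the
  test suite asserts);
* `λ_max` computed from the score at β = 0 so the all-zero solution is
  exactly KKT-stationary there; the path is log-spaced down to
  `min_ratio·λ_max` (0.05 when P > N, else 0.01);
* sequential strong-rule screening along the path with a full
  Karush–Kuhn–Tucker sweep after convergence; screening failures are
  re-solved with the violators added, so the returned solutions satisfy
  the KKT conditions regardless of the screen;
* step-halving toward the previous iterate whenever an IRLS step would
  increase the penalized objective, making the objective non-increasing
  across outer iterations (asserted within 1e-10 in tests);
* convergence tolerances on the weighted squared coefficient change:
  1e-8 within coordinate descent and across IRLS steps by default
  (1e-7 inside stability selection, where only the identity of the
  λ_min active set matters); coefficients below 1e-10 in absolute value
  are snapped to exact zeros, which keeps the all-zero solution exact at
  the λ_max boundary;
* a `dfmax` path bound: the path stops once a solution exceeds the
  requested number of nonzero coefficients.  Stability selection uses
  a third of the subsample size by default — the cross-validated
  deviance optimum for a sparse germline panel lies far below the
  near-saturated tail of the path, which is unidentifiable when
  P ≫ N and by far the most expensive stretch to compute.

Cross-validation uses the Verweij–Van Houwelingen cross-validated
partial likelihood: fold k contributes
`-2·(loglik_full(β_k) - loglik_train(β_k))`; `λ_min` minimizes the fold
mean, and the reported nonzero set is read off a full-data path at
`λ_min`.  Folds are a seeded permutation with sizes differing by at most
one; fold sets without events trigger a bounded, deterministic redraw.

## Stability selection

Each repeat draws ⌊0.9·N⌋ patients without replacement (fresh three-fold
split per repeat) and counts the SNPs selected at λ_min.  Per-repeat
seeds are fixed offsets from the master seed, so results are independent
of execution order.  Candidate aggregation follows two deliberately
different threshold conventions: LASSO candidates need *strictly more*
than 25% of repeats, elastic-net candidates need *at least* 70% — the
inclusivities differ because the two rules were stated that way in the
procedure this package operationalizes, and the boundary cases are
pinned by unit tests.  Genotypes enter the penalized model as additive
dosages with missing calls imputed to the SNP mean (preserving allele
frequency); clinical covariates are excluded from the selection model by
default but can be forced in unpenalized via `penalty_free_idx`.
Selected candidates then pass a post-selection Hardy–Weinberg screen:
a retained SNP requires an exact-test p strictly above 1e-4.

## Association and validation statistics

* **Hardy–Weinberg exact test** — the standard exact conditional test:
  given the allele counts, sum the probabilities of all heterozygote
  counts no more probable than the observed one.
* **Fisher r×c** — full enumeration over all tables with the observed
  margins (probability ordering), supported to 3×3; cross-checked
  exactly against the classical hypergeometric test.
* **Contingency chi-square** — Pearson, with Yates correction for 2×2
  tables only.  This convention reproduces the printed
  cohort-characteristics p-values embedded as fixtures
  (`table1_fixtures()`): 0.042, 0.10, 0.005, 0.14 and 1.  The printed
  sex-row value (0.78) is *not* reproduced by plain Pearson (which gives
  0.83); the variant used for that row is unknown, so it is excluded
  from the reproduction set.  KRAS tables include the "unknown" row;
  primary-site and BRAF tables exclude it — both choices mirror what
  reproduces the printed values, and both modes are available.
* **Permutation-corrected log-rank** — the corrected p is the plain
  frequency `#{p_b ≤ p_obs}/B` over seeded permutations of the genotype
  vector with survival fixed; an add-one-smoothed variant is available
  by flag.  Under the null the corrected p is uniform (checked by a
  Kolmogorov–Smirnov test across replicates).
* **LD** — two-locus haplotype frequencies by EM from unphased
  genotype pairs, double heterozygotes split by current phase odds,
  started from linkage equilibrium.  For two loci the likelihood is
  well behaved in this parameterization and multiple restarts are not
  used.  D′ scales D by its bound given allele frequencies; the
  auxiliary inequality |r| ≤ D′ is asserted on converged estimates.
* **Two-SNP combination** — the first SNP's minor homozygote takes
  precedence regardless of the second SNP (including when the second is
  missing); otherwise the second SNP's minor homozygote; otherwise the
  baseline of carrying a major allele at each locus.  Pooled analyses
  fit a single Cox model stratified by cohort (separate baseline
  hazards) — the conservative choice when cohorts differ in follow-up.

## Model evaluation

IPCW Brier scores use Graf-style weights: events before the horizon are
weighted `1/G(T⁻)` (left limit of the censoring Kaplan–Meier), patients
at risk past it `1/G(t)`, censored-before contribute zero; with no
censoring this reduces *exactly* to the mean squared error, which the
tests assert as an identity.  Prediction error curves use ordinary
out-of-bag bootstrap averaging (resample with replacement, fit on the
bag, score on the out-of-bag patients), B = 100 by default; the .632
variants are deliberately out of scope.

## The synthetic-cohort generator

Real cohorts for this class of study are under restricted access, so
the generator defines the study conditions: genotypes drawn as two
independent allele draws per patient (Hardy–Weinberg in expectation)
with a configurable MAF spectrum, LD blocks drawn as two haplotypes
from an explicit pool (validated against the marginal MAFs to 1e-6),
covariates (sex, age, KRAS status at trial-like marginals), and
exponential proportional-hazards PFS with planted SNP effects.
Defaults are chosen to resemble a first-line metastatic colorectal
cancer cohort: baseline median PFS 300 days, light independent
exponential censoring (rate log(2)/1200 per day), five-year
administrative censoring; OS is the PFS event time plus an independent
exponential residual sharing the SNP effects (median residual 420
days), so OS ≥ PFS by construction.  A Weibull shape option exists; the
exponential default keeps the censoring calibration analytic
(`P(event) = λ/(λ+µ)·(1−e^{−(λ+µ)a})`), which the tests verify against
Monte-Carlo error.  Missingness is completely at random — the coverage
filters the workflow implements contain no informative-missingness
model, so none is simulated.  The generator does not simulate
sequencing reads, genotype-calling error, or population stratification;
passing tests therefore say nothing about robustness to stratification
or differential genotyping error in real cohorts.

Effect sizes planted in the simulator are free parameters, not
calibrated claims: the study this workflow reimplements reports fitted
hazard ratios on restricted data, not generative effect sizes.

## Problem sizes in the test suite

Module tests run on small cohorts (tens to hundreds of patients).  The
end-to-end property suite uses: stability selection at N = 180,
P = 500 with a planted dominant HR 2.5 SNP (α = 0.5, 200 repeats, 50
replicate cohorts; planted selection frequency > 0.70 in ≥ 80% of
replicates, median null frequency < 0.10); Wald CI coverage over 500
cohorts of n = 2000 (93–97% band); permutation-test null uniformity
over 200 replicates at B = 500.  These sizes were chosen so each suite
demonstrates its property at comfortable Monte-Carlo resolution.

## Known limitations

* No time-varying covariates, frailty terms, or formal proportionality
  diagnostics.
* The penalized model codes genotypes additively; a purely recessive
  rare effect (minor-homozygote frequency of a few percent) is weakly
  visible to an additive LASSO at these cohort sizes, and the workflow
  relies on the explicitly coded association scan to characterize it —
  the bundled analysis scripts show exactly this behaviour.
* Fisher enumeration is limited to 3×3 tables by design; larger tables
  are refused rather than approximated.
* `cv_coxnet` reports the λ_min rule only; a one-standard-error rule
  would be a small extension but is not what the reimplemented
  procedure used.
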