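test_that("Fisher r x c enumeration matches hypergeometric and independence cases", {
  # 2x2 against the classical two-sided hypergeometric (probability method)
  tab <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact_rxc(tab), fisher.test(tab)$p.value,
               tolerance = 1e-12)
  # proportional rows: independence, p = 1
  expect_equal(fisher_exact_rxc(matrix(c(10, 20, 30, 60), 2, byrow = TRUE)), 1)
  # identical genotype distributions in a 3x2
  expect_equal(fisher_exact_rxc(cbind(c(20, 10, 5), c(20, 10, 5))), 1)
  expect_error(fisher_exact_rxc(matrix(1, 4, 2)), "3x3")
  expect_error(fisher_exact_rxc(matrix(0, 2, 2)), "empty")
})

test_that("Fisher enumeration equals fisher.test on random small tables", {
  set.seed(31)
  for (i in 1:40) {
    r <- sample(2:3, 1); cc <- sample(2:3, 1)
    tab <- matrix(rpois(r * cc, 4), r, cc)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("contingency chi-square reproduces the cohort characteristics table", {
  t1 <- table1_fixtures()
  p <- function(tab, yates = TRUE) chisq_contingency(tab, yates)$p
  expect_equal(round(p(t1$backbone), 3), 0.042)
  expect_equal(round(p(t1$kras_with_unknown), 2), 0.10)
  expect_equal(round(p(t1$site_excl_unknown), 3), 0.005)
  expect_equal(round(p(t1$braf_excl_unknown), 2), 0.14)
  expect_equal(p(t1$adjuvant), 1)
  # Yates never increases the statistic
  s_y <- chisq_contingency(t1$adjuvant, TRUE)$statistic
  s_n <- chisq_contingency(t1$adjuvant, FALSE)$statistic
  expect_lte(s_y, s_n)
  expect_error(chisq_contingency(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("LD estimation: identity, independence and phased-collapse oracle", {
  set.seed(41)
  codes <- cbind(rbinom(300, 2, 0.3), rbinom(300, 2, 0.4))
  gm <- make_gm(codes, ids = c("s1", "s2"))
  self <- ld_pair(gm, "s1", "s1")
  expect_equal(self$Dprime, 1, tolerance = 1e-9)
  expect_equal(self$r, 1, tolerance = 1e-9)
  # independent SNPs at n = 5000
  big <- make_gm(cbind(rbinom(5000, 2, 0.3), rbinom(5000, 2, 0.4)),
                 ids = c("a", "b"))
  indep <- ld_pair(big, "a", "b")
  expect_lt(abs(indep$r), 0.05)
  # haplotype pairs collapsed to genotypes with no double heterozygotes:
  # EM must equal direct haplotype counting
  haps <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  pairs <- rbind(c(1, 1), c(1, 2), c(2, 2), c(3, 3), c(3, 4), c(4, 4),
                 c(1, 1), c(4, 4), c(2, 2), c(1, 2))
  g <- haps[pairs[, 1], ] + haps[pairs[, 2], ]
  gmh <- make_gm(g, ids = c("h1", "h2"))
  est <- ld_pair(gmh, "h1", "h2")
  hap_counts <- table(factor(c(pairs), levels = 1:4))
  direct <- as.numeric(hap_counts) / sum(hap_counts)
  expect_equal(unname(est$hap), direct, tolerance = 1e-9)
  # |r| <= D' on EM-converged estimates
  expect_lte(abs(est$r), est$Dprime + 1e-9)
  expect_error(ld_pair(make_gm(cbind(rep(0, 10), rbinom(10, 2, 0.4)),
                               ids = c("m", "v")), "m", "v"),
               "monomorphic")
})

test_that("perfect-LD construction from a two-haplotype pool", {
  specs <- rbind(snp_spec("x1", 0.5), snp_spec("x2", 0.5))
  block <- ld_block_spec("b1", c("x1", "x2"),
                         rbind(c(0, 0), c(1, 1)), c(0.5, 0.5))
  gm <- simulate_genotypes(400, specs, ld_blocks = list(block), seed = 3)
  est <- ld_pair(gm, "x1", "x2")
  expect_equal(est$Dprime, 1, tolerance = 1e-9)
  expect_equal(abs(est$r), 1, tolerance = 1e-9)
})

test_that("two-SNP grouping follows the precedence rules", {
  codes <- rbind(
    c(2, 2), c(2, 0), c(2, NA),  # snp1 hom-minor takes precedence
    c(1, 2), c(0, 2),            # snp2 hom-minor
    c(0, 0), c(1, 1),            # baseline
    c(NA, 2), c(0, NA)           # unassigned
  )
  gm <- make_gm(codes, ids = c("s1", "s2"))
  lab <- two_snp_groups(gm, "s1", "s2")
  expect_equal(as.character(lab),
               c("snp1_hom_minor", "snp1_hom_minor", "snp1_hom_minor",
                 "snp2_hom_minor", "snp2_hom_minor",
                 "baseline", "baseline",
                 "unassigned", "unassigned"))
})

test_that("combined-group association recovers a planted group hazard", {
  set.seed(51)
  n <- 600
  lab <- factor(sample(c("baseline", "snp2_hom_minor", "snp1_hom_minor"),
                       n, TRUE, c(0.7, 0.15, 0.15)),
                levels = c("baseline", "snp2_hom_minor", "snp1_hom_minor",
                           "unassigned"))
  hr <- c(baseline = 1, snp2_hom_minor = 3, snp1_hom_minor = 0.5)
  t <- rexp(n, 0.002 * hr[as.character(lab)])
  cl <- make_clinical(pmin(t, 1500), as.integer(t <= 1500))
  res <- combined_group_association(lab, cl)
  expect_false(any(res$cox$inestimable))
  expect_gt(res$cox$hr[res$cox$term == "snp2_hom_minor"], 2)
  expect_lt(res$cox$hr[res$cox$term == "snp1_hom_minor"], 0.8)
  expect_equal(res$logrank$df, 2)
  # permutation of patient order leaves estimates unchanged
  perm <- sample(n)
  res2 <- combined_group_association(lab[perm], cl[perm, ], )
  expect_equal(res2$cox$hr, res$cox$hr, tolerance = 1e-9)
  # all-baseline labels: both contrasts inestimable
  lab0 <- factor(rep("baseline", 50),
                 levels = levels(lab))
  cl0 <- make_clinical(rexp(50, 0.01), rep(1, 50))
  res0 <- combined_group_association(lab0, cl0)
  expect_true(all(res0$cox$inestimable))
})

test_that("permutation-corrected log-rank is deterministic and label-invariant", {
  coh <- make_planted_cohort(n = 150, p = 3, log_hr = log(2), seed = 61)
  a <- permutation_corrected_logrank(coh$gm, "snp001", coh$clinical,
                                     B = 200, seed = 5)
  b <- permutation_corrected_logrank(coh$gm, "snp001", coh$clinical,
                                     B = 200, seed = 5)
  expect_identical(a, b)
  expect_gte(a$corrected_p, 0)
  # relabeling genotype categories leaves the corrected p unchanged
  gm2 <- coh$gm
  gm2$codes[, "snp001"] <- 2L - gm2$codes[, "snp001"]
  c_ <- permutation_corrected_logrank(gm2, "snp001", coh$clinical,
                                      B = 200, seed = 5)
  expect_equal(a$raw_p, c_$raw_p, tolerance = 1e-12)
  expect_equal(a$corrected_p, c_$corrected_p)
  # monomorphic genotype is an error
  gm3 <- coh$gm
  gm3$codes[, "snp002"] <- 0L
  expect_error(permutation_corrected_logrank(gm3, "snp002", coh$clinical),
               "single group")
})

test_that("a perfectly separating genotype has tiny corrected p", {
  n <- 60
  g <- rep(c(0L, 2L), each = n / 2)
  gm <- make_gm(matrix(g, ncol = 1), ids = "sep")
  # group 2 fails much earlier, complete separation of event times
  cl <- make_clinical(c(seq(1000, 1290, by = 10), seq(1, 291, by = 10)),
                      rep(1, n))
  res <- permutation_corrected_logrank(gm, "sep", cl, B = 1000, seed = 9)
  expect_lte(res$corrected_p, 0.001)
  sm <- permutation_corrected_logrank(gm, "sep", cl, B = 1000, seed = 9,
                                      smoothed = TRUE)
  expect_equal(sm$corrected_p, (1 + 1000 * res$corrected_p) / 1001)
})

test_that("adjusted scan restricts subgroups exactly and flags monomorphic SNPs", {
  coh <- make_planted_cohort(n = 400, p = 4, log_hr = log(2), seed = 71)
  wt_n <- sum(coh$clinical$kras == "wt")
  scan <- adjusted_scan("snp001", coh$gm, coh$clinical,
                        covariates = c("sex", "age"), endpoint = "pfs",
                        models = "dominant",
                        subgroup = list(kras = "wt"))
  expect_equal(scan$n_used, wt_n)
  # monomorphic within the subgroup: flagged, not dropped
  gm <- coh$gm
  gm$codes[, "snp002"] <- 0L
  scan2 <- adjusted_scan(c("snp001", "snp002"), gm, coh$clinical,
                         endpoint = "pfs", models = "dominant")
  expect_equal(nrow(scan2), 2)
  expect_true(scan2$inestimable[scan2$snp_id == "snp002"])
  expect_error(adjusted_scan(character(0), coh$gm, coh$clinical),
               "no candidates")
})

test_that("genotype distribution test is 1 for a cohort against itself", {
  coh <- make_planted_cohort(n = 80, p = 3, seed = 81)
  for (s in coh$gm$snps$snp_id) {
    expect_equal(genotype_distribution_test(coh$gm, coh$gm, s), 1,
                 tolerance = 1e-9)
  }
})
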