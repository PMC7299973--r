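# Small in-code fixtures shared across test files.

# genotype matrix from a bare code matrix (patients x SNPs)
make_gm <- function(codes, ids = NULL) {
  codes <- as.matrix(codes)
  if (is.null(ids)) ids <- sprintf("rs%03d", seq_len(ncol(codes)))
  genotype_matrix(
    codes,
    data.frame(snp_id = ids, chrom = "1", pos = seq_along(ids) * 100L,
               ref = "A", alt = "B", minor = "B", gene = toupper(ids),
               stringsAsFactors = FALSE)
  )
}

# minimal clinical table wrapping given outcomes
make_clinical <- function(time, event, os_time = time * 2,
                          os_event = event, ids = NULL, extra = NULL) {
  n <- length(time)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  cl <- data.frame(patient_id = ids, pfs_time = time, pfs_event = event,
                   os_time = os_time, os_event = os_event,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) cl <- cbind(cl, extra)
  cl
}

# a small simulated cohort with one planted dominant effect on snp001
make_planted_cohort <- function(n = 300, p = 10, maf = 0.3,
                                log_hr = log(2), seed = 1,
                                model = "dominant") {
  specs <- do.call(rbind, lapply(seq_len(p), function(i) {
    snp_spec(sprintf("snp%03d", i), maf = maf, gene = sprintf("G%03d", i))
  }))
  simulate_cohort(
    n, specs,
    effects = list(effect_spec("snp001", model, log_hr)),
    seed = seed
  )
}

# independent enumeration oracle for the Hardy-Weinberg exact test:
# direct conditional probabilities over every feasible heterozygote count
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n1 <- 2 * n_bb + n_ab
  n2 <- 2 * n - n1
  if (n1 == 0 || n2 == 0) return(1)
  rare <- min(n1, n2)
  hs <- seq(rare %% 2, rare, by = 2)
  probs <- vapply(hs, function(h) {
    exp(lfactorial(n) - lfactorial((n1 - h) / 2) - lfactorial(h) -
          lfactorial((n2 - h) / 2) + h * log(2) +
          lfactorial(n1) + lfactorial(n2) - lfactorial(2 * n))
  }, numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, hs)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}
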