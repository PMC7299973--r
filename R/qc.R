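#' Hardy-Weinberg exact test
#'
#' Exact conditional test for departure from Hardy-Weinberg genotype
#' proportions at a biallelic locus.  Conditional on the observed allele
#' counts, the p-value sums the probabilities of all heterozygote counts
#' whose conditional probability does not exceed that of the observed
#' count (two-sided by probability ordering).
#'
#' @param n_hom_major,n_het,n_hom_minor non-negative genotype counts.
#' @return The exact p-value in `[0, 1]`; a monomorphic locus gives 1.
#' @export
hwe_exact_p <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  n1 <- 2 * n_hom_minor + n_het          # minor allele copies
  n2 <- 2 * n - n1
  if (n1 == 0 || n2 == 0) return(1)
  rare <- min(n1, n2)
  h <- seq(rare %% 2, rare, by = 2)      # feasible heterozygote counts
  # log P(het = h | allele counts), up to the common normalizing constant
  logp <- h * log(2) - lgamma((n1 - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((n2 - h) / 2 + 1)
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  obs <- p[match(n_het, h)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele parity",
                       call. = FALSE)
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Per-SNP Hardy-Weinberg p-values for a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @return Named numeric vector of [hwe_exact_p()] values (monomorphic or
#'   all-missing SNPs give 1).
#' @export
gm_hwe <- function(gm) {
  vapply(seq_len(ncol(gm$codes)), function(j) {
    g <- gm$codes[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_p(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(gm$snps$snp_id)
}

#' Discovery-cohort SNP inclusion filter
#'
#' Applies the four discovery inclusion criteria:
#' carrier frequency (fraction of patients carrying at least one minor
#' allele) at least `min_carrier` and strictly below 1; reference MAF at
#' least `min_ref_maf` (a SNP absent from the reference table fails);
#' call rate (non-missing fraction) at least `min_call_rate`; and a unique
#' gene annotation.  Carrier frequency is computed over non-missing
#' patients by default (`carrier_denominator = "nonmissing"`), or over all
#' patients with `"all"`.
#'
#' @param gm a [genotype_matrix()].
#' @param ref_maf named numeric vector of reference MAFs
#'   (see [read_maf_table()]); may lack entries.
#' @param gene_map optional data.frame (`snp_id`, `gene`); when `NULL` the
#'   matrix's own `gene` metadata is used (a non-`NA` gene counts as
#'   unique).
#' @param min_carrier,min_ref_maf,min_call_rate thresholds, all inclusive
#'   on the "at least" side.
#' @param carrier_denominator `"nonmissing"` or `"all"`.
#' @return A `qc_report`: data.frame with per-SNP flags and p-values, and
#'   attribute `kept` holding the ids passing all four criteria.
#' @export
discovery_filter <- function(gm, ref_maf, gene_map = NULL,
                             min_carrier = 0.10, min_ref_maf = 0.05,
                             min_call_rate = 0.90,
                             carrier_denominator = c("nonmissing", "all")) {
  carrier_denominator <- match.arg(carrier_denominator)
  if (!is.null(gene_map)) gm <- gm_annotate(gm, gene_map)
  codes <- gm$codes
  n <- nrow(codes)
  if (n == 0L || ncol(codes) == 0L) {
    stop("empty genotype matrix", call. = FALSE)
  }
  nonmiss <- colSums(!is.na(codes))
  carriers <- colSums(codes >= 1L, na.rm = TRUE)
  denom <- if (carrier_denominator == "nonmissing") nonmiss else n
  carrier_freq <- ifelse(denom > 0, carriers / denom, 0)
  call_rate <- nonmiss / n

  rmaf <- ref_maf[gm$snps$snp_id]
  report <- data.frame(
    snp_id = gm$snps$snp_id,
    carrier_freq = carrier_freq,
    call_rate = call_rate,
    ref_maf = as.numeric(rmaf),
    hwe_p = gm_hwe(gm),
    carrier_freq_pass = carrier_freq >= min_carrier & carrier_freq < 1,
    ref_maf_pass = !is.na(rmaf) & rmaf >= min_ref_maf,
    call_rate_pass = call_rate >= min_call_rate,
    unique_gene_pass = !is.na(gm$snps$gene),
    stringsAsFactors = FALSE
  )
  report$kept <- report$carrier_freq_pass & report$ref_maf_pass &
    report$call_rate_pass & report$unique_gene_pass
  rownames(report) <- NULL
  structure(report,
            kept = report$snp_id[report$kept],
            class = c("qc_report", "data.frame"))
}

#' Validation-cohort coverage filter
#'
#' Keeps SNPs whose non-missing fraction is at least `min_call_rate`
#' (boundary inclusive).
#'
#' @param gm a [genotype_matrix()].
#' @param min_call_rate minimum covered fraction, default 0.80.
#' @return Character vector of kept SNP ids.
#' @export
validation_filter <- function(gm, min_call_rate = 0.80) {
  if (nrow(gm$codes) == 0L) stop("empty genotype matrix", call. = FALSE)
  call_rate <- colMeans(!is.na(gm$codes))
  gm$snps$snp_id[call_rate >= min_call_rate]
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report` from [discovery_filter()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
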