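#' Genotype matrix container
#'
#' Bundles an N patients x P SNPs matrix of minor-allele counts
#' (0, 1, 2 or `NA` for a missing call) with per-SNP metadata.  Alleles are
#' oriented so that the *minor* allele (sample frequency <= 0.5) is the
#' counted allele; ties at 0.5 count the ALT allele.
#'
#' @param codes integer matrix, patients in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param snps data.frame with one row per SNP and columns `snp_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `minor` (the counted allele), `gene`
#'   (may be `NA`).
#' @param patient_ids character vector of unique patient identifiers, one
#'   per row of `codes`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `codes`, `snps`, `patient_ids`.
#' @export
genotype_matrix <- function(codes, snps, patient_ids = rownames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(patient_ids)) {
    patient_ids <- sprintf("P%04d", seq_len(nrow(codes)))
  }
  patient_ids <- as.character(patient_ids)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos", "ref", "alt", "minor", "gene")
  for (col in setdiff(required, names(snps))) {
    snps[[col]] <- switch(col,
      chrom = "1", pos = seq_len(nrow(snps)),
      ref = "A", alt = "B", minor = "B", gene = NA_character_,
      stop("snps metadata must contain a 'snp_id' column", call. = FALSE)
    )
  }
  if (length(patient_ids) != nrow(codes)) {
    stop("patient_ids must match the number of rows of codes", call. = FALSE)
  }
  if (nrow(snps) != ncol(codes)) {
    stop("snps metadata must have one row per column of codes", call. = FALSE)
  }
  if (anyDuplicated(patient_ids)) {
    stop("duplicate patient ids", call. = FALSE)
  }
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp ids", call. = FALSE)
  }
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  rownames(codes) <- patient_ids
  colnames(codes) <- snps$snp_id
  structure(
    list(codes = codes, snps = snps, patient_ids = patient_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d patients x %d SNPs (%.1f%% missing)\n",
    nrow(x$codes), ncol(x$codes), 100 * mean(is.na(x$codes))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix by patients and/or SNPs
#'
#' @param gm a [genotype_matrix()].
#' @param patients patient ids or logical/integer index over patients.
#' @param snps SNP ids or logical/integer index over SNPs.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
gm_subset <- function(gm, patients = NULL, snps = NULL) {
  pi <- seq_len(nrow(gm$codes))
  si <- seq_len(ncol(gm$codes))
  if (!is.null(patients)) {
    pi <- if (is.character(patients)) {
      match(patients, gm$patient_ids)
    } else {
      pi[patients]
    }
    if (anyNA(pi)) stop("unknown patient id in subset", call. = FALSE)
  }
  if (!is.null(snps)) {
    si <- if (is.character(snps)) match(snps, gm$snps$snp_id) else si[snps]
    if (anyNA(si)) stop("unknown snp id in subset", call. = FALSE)
  }
  genotype_matrix(
    gm$codes[pi, si, drop = FALSE],
    gm$snps[si, , drop = FALSE],
    gm$patient_ids[pi]
  )
}

#' Sample minor-allele frequency of each SNP
#'
#' Computed over non-missing calls: half the mean minor-allele count.
#'
#' @param gm a [genotype_matrix()].
#' @return Named numeric vector of frequencies in `[0, 1]` (a value above
#'   0.5 indicates an unoriented matrix).
#' @export
gm_maf <- function(gm) {
  colMeans(gm$codes, na.rm = TRUE) / 2
}

#' Orient alleles so the counted allele is the minor one
#'
#' SNPs whose counted-allele sample frequency exceeds 0.5 have their codes
#' flipped (`2 - code`) and their `minor` metadata swapped to the other
#' allele.  Ties at exactly 0.5 keep the ALT allele as minor.  Orienting an
#' already-oriented matrix changes nothing.
#'
#' @param gm a [genotype_matrix()].
#' @return An oriented `genotype_matrix`.
#' @export
gm_orient <- function(gm) {
  freq <- gm_maf(gm)
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    gm$codes[, flip] <- 2L - gm$codes[, flip, drop = FALSE]
    other <- ifelse(gm$snps$minor == gm$snps$alt, gm$snps$ref, gm$snps$alt)
    gm$snps$minor[flip] <- other[flip]
  }
  gm
}

#' Encode one SNP under a genetic model
#'
#' Translates minor-allele counts into the regression coding used by the
#' association models: `additive` returns the 0/1/2 count itself,
#' `dominant` indicates carriage of at least one minor allele, `recessive`
#' indicates the minor homozygote, and `codominant` returns a two-column
#' matrix of indicators (heterozygote, minor homozygote) with the major
#' homozygote as reference.  Missing calls propagate as `NA`.
#'
#' With `flip = TRUE` the roles of the two alleles are exchanged before
#' encoding, so carrier groups can be defined with respect to the *major*
#' allele (e.g. "any major-allele carrier" as the exposed group).
#'
#' @param gm a [genotype_matrix()].
#' @param snp_id SNP identifier.
#' @param model one of `"additive"`, `"dominant"`, `"recessive"`,
#'   `"codominant"`.
#' @param flip swap allele roles before encoding.
#' @return A numeric vector, or a two-column matrix for `codominant`.
#' @export
encode <- function(gm, snp_id,
                   model = c("additive", "dominant", "recessive",
                             "codominant"),
                   flip = FALSE) {
  model <- match.arg(model)
  j <- match(snp_id, gm$snps$snp_id)
  if (is.na(j)) stop("unknown snp_id: ", snp_id, call. = FALSE)
  g <- gm$codes[, j]
  if (flip) g <- 2L - g
  switch(model,
    additive  = as.numeric(g),
    dominant  = as.numeric(g >= 1L),
    recessive = as.numeric(g == 2L),
    codominant = {
      out <- cbind(het = as.numeric(g == 1L), hom_minor = as.numeric(g == 2L))
      rownames(out) <- gm$patient_ids
      out
    }
  )
}
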