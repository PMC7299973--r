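#' Read a genotype matrix from a VCF file
#'
#' Parses the VCF v4.x subset used throughout the pipeline: biallelic
#' records with a `GT` entry in FORMAT.  Phasing separators `/` and `|`
#' are treated identically; `./.` (or `.`) is a missing call.  After
#' parsing, alleles are oriented so the counted allele is the minor one in
#' the file (frequency tie at 0.5: ALT counts).
#'
#' @param path path to a plain-text VCF file.
#' @return A [genotype_matrix()].  Gene annotations are `NA`; attach them
#'   with [read_gene_map()] + [gm_annotate()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) {
    stop("not a VCF file: missing #CHROM header line", call. = FALSE)
  }
  header <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10L) {
    # header-only file with no samples is still valid but empty
    if (length(header) < 8L) {
      stop("malformed #CHROM header line", call. = FALSE)
    }
  }
  sample_ids <- if (length(header) > 9L) header[-(1:9)] else character(0)
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]

  n_snp <- length(body)
  codes <- matrix(NA_integer_, nrow = length(sample_ids), ncol = n_snp)
  snps <- data.frame(
    snp_id = character(n_snp), chrom = character(n_snp),
    pos = integer(n_snp), ref = character(n_snp), alt = character(n_snp),
    minor = character(n_snp), gene = rep(NA_character_, n_snp),
    stringsAsFactors = FALSE
  )

  for (k in seq_len(n_snp)) {
    lineno <- hdr + k
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L + length(sample_ids)) {
      stop(sprintf("VCF line %d: too few fields", lineno), call. = FALSE)
    }
    if (grepl(",", f[5], fixed = TRUE)) {
      stop(sprintf("VCF line %d: multiallelic records are unsupported", lineno),
           call. = FALSE)
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) {
      stop(sprintf("VCF line %d: FORMAT lacks GT", lineno), call. = FALSE)
    }
    if (length(sample_ids)) {
      gt <- vapply(
        strsplit(f[-(1:9)], ":", fixed = TRUE),
        function(x) x[gt_idx], ""
      )
      alleles <- strsplit(gt, "[/|]")
      codes[, k] <- vapply(seq_along(alleles), function(i) {
        a <- alleles[[i]]
        if (all(a == ".")) return(NA_integer_)
        if (length(a) != 2L || !all(a %in% c("0", "1"))) {
          stop(sprintf("VCF line %d: malformed GT '%s'", lineno, gt[i]),
               call. = FALSE)
        }
        sum(a == "1")
      }, integer(1))
    }
    snps$snp_id[k] <- if (f[3] == ".") sprintf("%s:%s", f[1], f[2]) else f[3]
    snps$chrom[k] <- f[1]
    snps$pos[k] <- as.integer(f[2])
    snps$ref[k] <- f[4]
    snps$alt[k] <- f[5]
    snps$minor[k] <- f[5]
  }
  gm_orient(genotype_matrix(codes, snps, sample_ids))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits the VCF v4.2 subset read by [read_vcf()] (CHROM, POS, ID, REF,
#' ALT, FORMAT `GT`); reading the file back reproduces codes and metadata
#' exactly.  Codes count the matrix's minor allele, so GT strings are
#' written with respect to REF/ALT: if the minor allele is REF, a code of
#' 2 becomes `0/0`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$patient_ids), collapse = "\t")
  ), con)
  gt_map_alt <- c("0/0", "0/1", "1/1")
  gt_map_ref <- c("1/1", "0/1", "0/0")
  for (k in seq_len(ncol(gm$codes))) {
    s <- gm$snps[k, ]
    map <- if (s$minor == s$alt) gt_map_alt else gt_map_ref
    g <- gm$codes[, k]
    gt <- ifelse(is.na(g), "./.", map[g + 1L])
    writeLines(paste(c(s$chrom, s$pos, s$snp_id, s$ref, s$alt, ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' The table must contain a `patient_id` column plus the survival
#' endpoints `pfs_time`, `pfs_event` and (optionally) `os_time`,
#' `os_event`; times are in days, events are 0/1.  All other columns are
#' covariates; character columns become factors.
#'
#' @param path TSV path.
#' @return A data.frame with factors for categorical covariates.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"patient_id" %in% names(cl)) {
    stop("clinical table lacks a patient_id column", call. = FALSE)
  }
  needed <- c("pfs_time", "pfs_event")
  miss <- setdiff(needed, names(cl))
  if (length(miss)) {
    stop("clinical table lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in names(cl)) {
    if (is.character(cl[[col]]) && col != "patient_id") {
      cl[[col]] <- factor(cl[[col]])
    }
  }
  check_clinical(cl)
  cl
}

check_clinical <- function(cl) {
  for (ep in c("pfs", "os")) {
    tcol <- paste0(ep, "_time")
    ecol <- paste0(ep, "_event")
    if (tcol %in% names(cl)) {
      if (any(cl[[tcol]] < 0, na.rm = TRUE)) {
        stop(tcol, " must be non-negative", call. = FALSE)
      }
      if (!all(cl[[ecol]] %in% c(0, 1, NA))) {
        stop(ecol, " must be 0/1", call. = FALSE)
      }
    }
  }
  if (anyDuplicated(cl$patient_id)) {
    stop("duplicate patient_id in clinical table", call. = FALSE)
  }
  invisible(cl)
}

#' Write a clinical table as TSV
#'
#' @param clinical data.frame as returned by [read_clinical()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference minor-allele-frequency table
#'
#' @param path TSV with columns `snp_id` and `maf` (e.g. 1000 Genomes
#'   European frequencies).
#' @return Named numeric vector of reference MAFs.
#' @export
read_maf_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$maf), tab$snp_id)
}

#' Read a SNP-to-gene annotation map
#'
#' @param path TSV with columns `snp_id` and `gene`.  A SNP may appear on
#'   several rows (ambiguous annotation); downstream filters treat that as
#'   a non-unique gene.
#' @return data.frame with columns `snp_id`, `gene`.
#' @export
read_gene_map <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)[, c("snp_id", "gene")]
}

#' Attach gene annotations to a genotype matrix
#'
#' SNPs mapped to exactly one gene get that gene; SNPs absent from the map
#' or mapped to several genes keep `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param gene_map data.frame from [read_gene_map()].
#' @return The annotated `genotype_matrix`.
#' @export
gm_annotate <- function(gm, gene_map) {
  counts <- table(gene_map$snp_id)
  unique_ids <- names(counts)[counts == 1L]
  map <- gene_map[gene_map$snp_id %in% unique_ids, ]
  idx <- match(gm$snps$snp_id, map$snp_id)
  gm$snps$gene <- ifelse(is.na(idx), NA_character_, map$gene[idx])
  gm
}
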