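test_that("VCF GT parsing follows the minor-allele coding", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"),
    paste("1", "100", "rs1", "A", "T", ".", "PASS", ".", "GT",
          "0/1", "0|0", "1/1", "./.", sep = "\t"),
    paste("1", "200", "rs2", "G", "C", ".", "PASS", ".", "GT",
          "0/0", "0/1", "0/0", "0/0", sep = "\t")
  ), path)
  gm <- read_vcf(path)
  # rs1: ALT frequency 3/6 = 0.5, tie -> ALT is minor
  expect_equal(unname(gm$codes[, "rs1"]), c(1L, 0L, 2L, NA))
  expect_equal(unname(gm$codes[, "rs2"]), c(0L, 1L, 0L, 0L))
  expect_equal(gm$snps$minor, c("T", "C"))
  expect_equal(gm$patient_ids, c("S1", "S2", "S3", "S4"))
})

test_that("alleles are re-oriented when ALT is the major allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", "S5", sep = "\t"),
    # ALT frequency 7/10 = 0.7 -> REF is minor, code 2 means hom-REF
    paste("1", "100", "rs9", "A", "G", ".", "PASS", ".", "GT",
          "1/1", "1/1", "1/1", "0/1", "0/0", sep = "\t")
  ), path)
  gm <- read_vcf(path)
  expect_equal(gm$snps$minor, "A")
  expect_equal(unname(gm$codes[, 1]), c(0L, 0L, 0L, 1L, 2L))
  # round trip preserves codes and metadata exactly
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, out)
  gm2 <- read_vcf(out)
  expect_identical(gm2$codes, gm$codes)
  expect_identical(gm2$snps, gm$snps)
  # orientation is idempotent
  expect_identical(gm_orient(gm)$codes, gm$codes)
})

test_that("VCF round trip is exact, including missing calls and empty files", {
  gm <- make_gm(rbind(c(0, 2), c(1, NA), c(2, 0)))
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, out)
  back <- read_vcf(out)
  expect_identical(back$codes, gm$codes)
  expect_identical(back$snps$minor, gm$snps$minor)

  empty <- gm_subset(gm, snps = integer(0))
  out2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(empty, out2)
  back2 <- read_vcf(out2)
  expect_equal(ncol(back2$codes), 0L)
  expect_equal(back2$patient_ids, gm$patient_ids)
})

test_that("malformed and multiallelic records are rejected with line context", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("1", "100", "rs1", "A", "T,G", ".", "PASS", ".", "GT", "0/1",
          sep = "\t")
  ), path)
  expect_error(read_vcf(path), "multiallelic")
  expect_error(read_vcf(path), "line 3")

  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("1", "100", "rs1", "A", "T", ".", "PASS", ".", "GT", "0/2",
          sep = "\t")
  ), path)
  expect_error(read_vcf(path), "malformed GT")
})

test_that("genetic-model encodings follow their definitions", {
  gm <- make_gm(matrix(c(0, 1, 2, NA), ncol = 1))
  expect_equal(encode(gm, "rs001", "additive"), c(0, 1, 2, NA))
  expect_equal(encode(gm, "rs001", "dominant"), c(0, 1, 1, NA))
  expect_equal(encode(gm, "rs001", "recessive"), c(0, 0, 1, NA))
  cod <- encode(gm, "rs001", "codominant")
  expect_equal(unname(cod[, "het"]), c(0, 1, 0, NA))
  expect_equal(unname(cod[, "hom_minor"]), c(0, 0, 1, NA))
  # flip swaps allele roles: dominant w.r.t. the major allele
  expect_equal(encode(gm, "rs001", "dominant", flip = TRUE), c(1, 1, 0, NA))
  expect_error(encode(gm, "nope", "additive"), "unknown snp_id")
})

test_that("additive code equals dominant plus recessive for complete calls", {
  set.seed(42)
  gm <- make_gm(matrix(sample(0:2, 200, TRUE), ncol = 4))
  for (id in gm$snps$snp_id) {
    expect_equal(encode(gm, id, "additive"),
                 encode(gm, id, "dominant") + encode(gm, id, "recessive"))
  }
})

test_that("clinical TSV round trips with type checks", {
  cl <- make_clinical(c(10, 20, 30), c(1, 0, 1),
                      extra = data.frame(sex = c("m", "f", "m")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clinical(cl, path)
  back <- read_clinical(path)
  expect_equal(back$pfs_time, cl$pfs_time)
  expect_s3_class(back$sex, "factor")
  bad <- cl
  bad$pfs_event[1] <- 2
  write_clinical(bad, path)
  expect_error(read_clinical(path), "0/1")
})

test_that("gene annotation keeps only uniquely mapped SNPs", {
  gm <- make_gm(matrix(0:2, nrow = 3, ncol = 3))
  map <- data.frame(snp_id = c("rs001", "rs002", "rs002"),
                    gene = c("GENE1", "GX", "GY"))
  ann <- gm_annotate(gm, map)
  expect_equal(ann$snps$gene, c("GENE1", NA, NA))
})

test_that("written VCFs are readable by an independent VCF parser", {
  skip_if_not_installed("vcfR")
  gm <- make_gm(rbind(c(0, 2), c(1, NA), c(2, 0), c(1, 1)))
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, out)
  v <- suppressWarnings(vcfR::read.vcfR(out, verbose = FALSE))
  gt <- vcfR::extract.gt(v)
  # minor allele is ALT here, so allele-1 counts match the codes
  counts <- apply(gt, 2, function(col) {
    vapply(strsplit(col, "[/|]"), function(a) {
      if (all(is.na(a))) NA_integer_ else sum(a == "1")
    }, integer(1))
  })
  expect_equal(unname(t(counts)), unname(gm$codes))
})
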