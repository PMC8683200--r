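test_that("dosage TSV round-trips to an identical genotype matrix", {
  G <- tiny_genotypes()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(G, path)
  G2 <- read_genotype_matrix(path, "tsv")
  expect_identical(G2$dosage, G$dosage)
  expect_identical(G2$snv_meta, G$snv_meta)
  # MISSING never coerces to 0
  expect_identical(sum(is.na(G2$dosage)), sum(is.na(G$dosage)))
})

test_that("TSV dosages outside {0,1,2} are rejected naming the cell", {
  G <- tiny_genotypes()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(G, path)
  tab <- readLines(path)
  tab[3] <- "S2\t3\t0"
  writeLines(tab, path)
  expect_error(read_genotype_matrix(path, "tsv"), "S2.*rs_a")
  expect_error(read_genotype_matrix("no/such/file.tsv", "tsv"), "not found")
})

test_that("VCF genotypes map GT fields to additive dosages", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "14\t37148248\trs_a\tT\tC\t.\tPASS\tGENE=SLC25A21\tGT\t0/1\t1|1\t./.",
    "3\t86118206\trs_b\tT\tA\t.\tPASS\tGENE=CADM2\tGT\t0/0\t./1\t1/0")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  G <- read_genotype_matrix(path, "vcf")
  expect_equal(unname(G$dosage["S1", "rs_a"]), 1)
  expect_equal(unname(G$dosage["S2", "rs_a"]), 2)
  expect_true(is.na(G$dosage["S3", "rs_a"]))   # ./. is missing
  expect_true(is.na(G$dosage["S2", "rs_b"]))   # half-call is missing
  expect_equal(unname(G$dosage["S3", "rs_b"]), 1)
  expect_equal(G$snv_meta$gene, c("SLC25A21", "CADM2"))
  expect_equal(G$snv_meta$pos, c(37148248L, 86118206L))
})

test_that("multi-allelic VCF records are rejected", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "14\t100\trs_m\tT\tC,G\t.\tPASS\t.\tGT\t1/2")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_error(read_genotype_matrix(path, "vcf"), "multi-allelic")
})

test_that("phenotype CSV round-trips and validates instrument ranges", {
  ph <- tiny_phenotypes()
  path <- withr::local_tempfile(fileext = ".csv")
  ph$gad7[2] <- NA
  write_phenotypes(validate_phenotypes(ph), path)
  back <- read_phenotypes(path)
  expect_equal(as.data.frame(back)$sample_id, ph$sample_id)
  expect_true(is.na(back$gad7[2]))
  expect_equal(back$audit_score, ph$audit_score)

  bad <- ph; bad$audit_score[1] <- 45L
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_phenotypes(path), "audit_score")

  dup <- ph; dup$sample_id[2] <- dup$sample_id[1]
  write.csv(dup, path, row.names = FALSE, na = "")
  expect_error(read_phenotypes(path), "duplicate")
})

test_that("report serialization is deterministic and JSON round-trips", {
  rep1 <- list(n = 157L, or_adj = c(snv1 = 2.0199999, alcohol = 0.63),
               note = "fixture")
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, p1, "json")
  write_report(rep1, p2, "json")
  expect_identical(readLines(p1), readLines(p2))
  back <- read_report(p1)
  expect_equal(back$n, 157L)
  expect_equal(back$or_adj[["snv1"]], signif(2.0199999, 6))

  df <- data.frame(variable = c("a", "b"), or = c(1.23456789, 2))
  pt <- withr::local_tempfile(fileext = ".tsv")
  write_report(df, pt, "tsv")
  expect_equal(read.delim(pt)$or[1], signif(1.23456789, 6))
})

test_that("genotype_matrix invariants are enforced", {
  meta <- tiny_genotypes()$snv_meta
  dos <- tiny_genotypes()$dosage
  bad_meta <- meta; bad_meta$ref[1] <- bad_meta$alt[1]
  expect_error(genotype_matrix(dos, bad_meta), "ref and alt")
  bad_meta <- meta; bad_meta$id <- c("x", "x")
  expect_error(genotype_matrix(dos, bad_meta), "duplicate SNV")
  bad_meta <- meta; bad_meta$pos[1] <- 0L
  expect_error(genotype_matrix(dos, bad_meta), ">= 1")
})
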