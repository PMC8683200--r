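#' @useDynLib cessnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm qnorm rbinom rnorm runif sd var
#' @importFrom utils read.csv read.delim write.csv write.table
NULL

MISSING_TOKEN <- "NA"

CANDIDATE_GENES <- c("IREB2", "SLC25A21", "SEMA6D", "CHRNA3", "CHRNA4",
                     "CHRNA5", "CHRNB4", "PSMA4", "DNMT3B", "CADM2",
                     "CYP2A6", "HTR2B")

EDUCATION_LEVELS <- c("less_than_hs", "hs_graduate", "some_college",
                      "college_graduate")

PHENO_COLUMNS <- c("sample_id", "outcome", "age", "gender", "race", "latino",
                   "education", "audit_score", "marijuana_30d", "cocaine_30d",
                   "cesd", "gad7")

#' Construct a genotype matrix
#'
#' A `genotype_matrix` couples an additive-coded dosage matrix (samples x
#' SNVs, entries 0/1/2 counting copies of the alternate allele, `NA` for a
#' missing call) with per-SNV metadata (chromosome, 1-based position,
#' reference and alternate alleles, gene symbol).
#'
#' @param dosage numeric matrix, rows = samples, columns = SNVs; entries in
#'   `{0, 1, 2, NA}`. Row names are sample ids, column names SNV ids.
#' @param snv_meta data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, one row per dosage column, in column order.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snv_meta) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  snv_meta <- as.data.frame(snv_meta, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "ref", "alt", "gene")
  if (!all(req %in% names(snv_meta)))
    stop("snv_meta must have columns: ", paste(req, collapse = ", "))
  snv_meta <- snv_meta[, req]
  if (nrow(snv_meta) != ncol(dosage))
    stop("snv_meta rows (", nrow(snv_meta), ") != dosage columns (",
         ncol(dosage), ")")
  if (anyDuplicated(snv_meta$id))
    stop("duplicate SNV ids in metadata")
  if (is.null(rownames(dosage)))
    stop("dosage must have sample ids as row names")
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate sample ids")
  if (any(snv_meta$pos < 1))
    stop("SNV positions must be >= 1 (1-based convention)")
  if (any(snv_meta$ref == snv_meta$alt))
    stop("ref and alt allele must differ")
  colnames(dosage) <- snv_meta$id
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("dosage outside {0,1,2} at sample '", rownames(dosage)[idx[1]],
         "', SNV '", colnames(dosage)[idx[2]], "'")
  }
  structure(list(dosage = dosage, snv_meta = snv_meta),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  cat("genotype_matrix: ", nrow(d), " samples x ", ncol(d), " SNVs (",
      sum(is.na(d)), " missing calls, ",
      length(unique(x$snv_meta$gene)), " genes)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Validate a participant phenotype data.frame
#'
#' Checks the column contract of a phenotype table (see
#' [read_phenotypes()] for the columns and instrument ranges), coerces
#' education to its ordered levels, and returns a `phenotype_table`.
#'
#' @param df data.frame with the phenotype columns.
#' @return A `phenotype_table`.
#' @export
validate_phenotypes <- function(df) {
  missing_cols <- setdiff(PHENO_COLUMNS, names(df))
  if (length(missing_cols))
    stop("phenotype table missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[, PHENO_COLUMNS]
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in phenotype table")
  if (!all(df$outcome %in% c("smoker", "ex_smoker")))
    stop("outcome must be 'smoker' or 'ex_smoker'")
  chk_range <- function(x, lo, hi, name) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad))
      stop(name, " out of instrument range [", lo, ", ", hi, "] for sample(s) ",
           paste(df$sample_id[bad], collapse = ", "))
  }
  chk_range(df$audit_score, 0, 40, "audit_score")
  chk_range(df$cesd, 0, 60, "cesd")
  chk_range(df$gad7, 0, 21, "gad7")
  bad_edu <- !is.na(df$education) & !(df$education %in% EDUCATION_LEVELS)
  if (any(bad_edu))
    stop("unknown education level: ",
         paste(unique(df$education[bad_edu]), collapse = ", "))
  df$education <- factor(df$education, levels = EDUCATION_LEVELS, ordered = TRUE)
  for (col in c("latino", "marijuana_30d", "cocaine_30d"))
    df[[col]] <- as.logical(df[[col]])
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a genotype matrix from a dosage TSV or a VCF
#'
#' The canonical interchange format is a tab-delimited dosage table (one row
#' per sample, first column `sample_id`, one column per SNV holding 0/1/2 or
#' `NA`) with a metadata sidecar `<path>.meta.tsv` mapping SNV id to
#' `(chrom, pos, ref, alt, gene)`. VCF (v4.x, GT field) is supported
#' read-only; the dosage is the alternate-allele count, half-calls and
#' unparseable genotypes become missing, and multi-allelic records are
#' rejected because the additive coding is strictly biallelic.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param meta_path metadata sidecar path for TSV input; defaults to
#'   `paste0(path, ".meta.tsv")`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, format = c("tsv", "vcf"),
                                 meta_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE, na.strings = MISSING_TOKEN,
                      colClasses = NA)
    if (names(tab)[1] != "sample_id") stop("first TSV column must be sample_id")
    dosage <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(dosage) <- "double"
    rownames(dosage) <- as.character(tab$sample_id)
    bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop("dosage outside {0,1,2} at row '", rownames(dosage)[idx[1]],
           "', column '", colnames(dosage)[idx[2]], "'")
    }
    if (is.null(meta_path)) meta_path <- paste0(path, ".meta.tsv")
    if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
    meta <- read.delim(meta_path, colClasses = "character")
    meta$pos <- as.integer(meta$pos)
    meta <- meta[match(colnames(dosage), meta$id), ]
    if (anyNA(meta$id)) stop("metadata sidecar missing some SNV ids")
    genotype_matrix(dosage, meta)
  } else {
    read_genotype_vcf(path)
  }
}

read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic VCF records are unsupported (strictly biallelic 0/1/2 coding)")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- fix$ID
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(fix$CHROM[blank], "_", fix$POS[blank])
  gene <- rep("other", nrow(fix))
  if (!is.null(fix$INFO)) {
    m <- regmatches(fix$INFO, regexpr("GENE=[^;]+", fix$INFO))
    has <- grepl("GENE=", fix$INFO)
    gene[has] <- sub("GENE=", "", m)
  }
  dosage <- matrix(gt_to_dosage(as.vector(gt)), nrow = nrow(gt))
  dosage <- t(dosage)  # samples x SNVs
  rownames(dosage) <- colnames(gt)
  meta <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, gene = gene,
                     stringsAsFactors = FALSE)
  genotype_matrix(dosage, meta)
}

# "0/0" -> 0, "0/1"/"1|0" -> 1, "1/1" -> 2; half-calls and anything
# unparseable -> NA
gt_to_dosage <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2 || any(!a %in% c("0", "1"))) return(NA_real_)
    sum(a == "1")
  }, numeric(1))
}

#' Write a genotype matrix as dosage TSV plus metadata sidecar
#'
#' @param G a [genotype_matrix()].
#' @param path output TSV path; the sidecar is written to
#'   `paste0(path, ".meta.tsv")`.
#' @export
write_genotype_matrix <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  tab <- data.frame(sample_id = rownames(G$dosage), G$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = MISSING_TOKEN)
  write.table(G$snv_meta, paste0(path, ".meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a participant phenotype table
#'
#' Expects a CSV with columns `sample_id`, `outcome` (`smoker` /
#' `ex_smoker`), `age`, `gender`, `race`, `latino`, `education` (ordered:
#' `less_than_hs`, `hs_graduate`, `some_college`, `college_graduate`),
#' `audit_score` (0-40), `marijuana_30d`, `cocaine_30d`, `cesd` (0-60),
#' `gad7` (0-21). Blank cells are missing. Instrument scores outside their
#' range and duplicated sample ids are rejected.
#'
#' @param path CSV path.
#' @return A `phenotype_table` (a validated data.frame).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  validate_phenotypes(df)
}

#' Write a phenotype table as CSV
#' @param pheno a `phenotype_table`.
#' @param path output CSV path.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- as.data.frame(pheno)
  out$education <- as.character(out$education)
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Serialize an analysis report deterministically
#'
#' Writes a report (any list / data.frame produced by the pipeline) as JSON
#' or TSV with stable key order and floats at 6 significant digits, so the
#' same report always serializes byte-identically.
#'
#' @param report list or data.frame.
#' @param path output path.
#' @param format `"json"` or `"tsv"` (TSV requires a data.frame).
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    json <- jsonlite::toJSON(round_floats(report), auto_unbox = TRUE,
                             digits = NA, na = "null", null = "null",
                             pretty = TRUE)
    writeLines(json, path)
  } else {
    if (!is.data.frame(report)) stop("TSV serialization requires a data.frame")
    out <- report
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], function(x) signif(x, 6))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = MISSING_TOKEN)
  }
  invisible(path)
}

round_floats <- function(x) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.double, logical(1))
    x[num] <- lapply(x[num], signif, 6)
    return(x)
  }
  if (is.list(x)) return(lapply(x, round_floats))
  # named atomic vectors keep their names as JSON object keys
  if (is.atomic(x) && !is.null(names(x)))
    return(lapply(as.list(x), round_floats))
  if (is.double(x)) return(signif(x, 6))
  x
}

#' Read back a JSON report written by [write_report()]
#' @param path JSON path.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
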