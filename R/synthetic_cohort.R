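#' Specification for a synthetic genotype-phenotype cohort
#'
#' Bundles the generator parameters: cohort size, SNV panel size and allele
#' frequency range, counts of planted low-variation / high-missingness /
#' duplicate-profile SNVs, count of participants with incomplete covariates,
#' linkage-disequilibrium block structure (Gaussian-copula correlation of
#' adjacent haplotypes), genetic and behavioral effects on the log-odds of
#' being an ex-smoker, and the baseline ex-smoker fraction.
#'
#' @param n_samples cohort size (default 194).
#' @param n_snvs SNV panel size (default 759).
#' @param maf_range minor-allele-frequency bounds for ordinary SNVs.
#' @param n_low_variation,n_high_missing,n_duplicate,n_incomplete_pheno
#'   planted pathology counts (defaults 124 / 458 / 21 / 37).
#' @param missing_rate_high per-SNV missing rate planted in high-missing
#'   columns (`>= 0.05`).
#' @param ld_block_size,ld_rho adjacent-SNV LD blocks: size and latent
#'   haplotype correlation.
#' @param causal_effects named numeric vector, SNV index (or id) to
#'   per-allele log-OR on the ex-smoker outcome.
#' @param behavioral_effects named numeric vector of log-ORs for
#'   `hazardous_alcohol`, `marijuana_30d`, `cocaine_30d`, `gad7` (per
#'   point).
#' @param baseline_prevalence target ex-smoker fraction (default 52/194).
#' @param seed integer RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 194, n_snvs = 759,
                        maf_range = c(0.05, 0.45),
                        n_low_variation = 124, n_high_missing = 458,
                        n_duplicate = 21, n_incomplete_pheno = 37,
                        missing_rate_high = 0.06,
                        ld_block_size = 5, ld_rho = 0.7,
                        causal_effects = numeric(0),
                        behavioral_effects = c(hazardous_alcohol = -1.0,
                                               marijuana_30d = -1.15,
                                               cocaine_30d = -2.4,
                                               gad7 = -0.08),
                        baseline_prevalence = 52 / 194,
                        seed = 1L) {
  spec <- list(n_samples = n_samples, n_snvs = n_snvs, maf_range = maf_range,
               n_low_variation = n_low_variation,
               n_high_missing = n_high_missing, n_duplicate = n_duplicate,
               n_incomplete_pheno = n_incomplete_pheno,
               missing_rate_high = missing_rate_high,
               ld_block_size = ld_block_size, ld_rho = ld_rho,
               causal_effects = causal_effects,
               behavioral_effects = behavioral_effects,
               baseline_prevalence = baseline_prevalence, seed = seed)
  if (n_low_variation + n_high_missing + n_duplicate >= n_snvs)
    stop("planted pathological SNVs must number fewer than n_snvs")
  if (n_duplicate >= n_snvs - n_low_variation - n_high_missing - n_duplicate)
    stop("more duplicates than available partner columns")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("baseline_prevalence must be in (0, 1)")
  if (missing_rate_high < 0.05)
    stop("missing_rate_high must be >= 0.05")
  if (n_incomplete_pheno >= n_samples)
    stop("n_incomplete_pheno must be < n_samples")
  class(spec) <- "cohort_spec"
  spec
}

snv_metadata_frame <- function(n_snvs) {
  gene_chrom <- c(IREB2 = "15", SLC25A21 = "14", SEMA6D = "15",
                  CHRNA3 = "15", CHRNA4 = "20", CHRNA5 = "15",
                  CHRNB4 = "15", PSMA4 = "15", DNMT3B = "20",
                  CADM2 = "3", CYP2A6 = "19", HTR2B = "2")
  gene_start <- c(IREB2 = 78729773, SLC25A21 = 37148248, SEMA6D = 47476298,
                  CHRNA3 = 78885394, CHRNA4 = 63343222, CHRNA5 = 78857862,
                  CHRNB4 = 78916636, PSMA4 = 78832747, DNMT3B = 31350191,
                  CADM2 = 85008927, CYP2A6 = 41349443, HTR2B = 231108231)
  genes <- rep(names(gene_chrom), length.out = n_snvs)
  within_gene <- stats::ave(seq_len(n_snvs), genes, FUN = seq_along)
  bases <- c("A", "C", "G", "T")
  ref <- bases[(seq_len(n_snvs) %% 4) + 1]
  alt <- bases[((seq_len(n_snvs) + 1) %% 4) + 1]
  data.frame(id = sprintf("snv%04d", seq_len(n_snvs)),
             chrom = unname(gene_chrom[genes]),
             pos = unname(gene_start[genes]) + 137L * (within_gene - 1L),
             ref = ref, alt = alt, gene = genes, stringsAsFactors = FALSE)
}

# Hardy-Weinberg genotypes with Gaussian-copula LD in adjacent blocks:
# two latent haplotype normals per individual share a block factor with
# loading sqrt(ld_rho); an allele is the event Phi(z) < maf.
draw_genotypes <- function(n, mafs, ld_block_size, ld_rho) {
  p <- length(mafs)
  dos <- matrix(0, n, p)
  block <- (seq_len(p) - 1) %/% ld_block_size
  for (b in unique(block)) {
    idx <- which(block == b)
    z_common <- cbind(rnorm(n), rnorm(n))     # one factor per haplotype
    for (j in idx) {
      z1 <- sqrt(ld_rho) * z_common[, 1] + sqrt(1 - ld_rho) * rnorm(n)
      z2 <- sqrt(ld_rho) * z_common[, 2] + sqrt(1 - ld_rho) * rnorm(n)
      thr <- qnorm(mafs[j])
      dos[, j] <- (z1 < thr) + (z2 < thr)
    }
  }
  dos
}

#' Generate a synthetic genotype-phenotype cohort
#'
#' Ordinary SNVs are drawn under Hardy-Weinberg equilibrium with MAF uniform
#' in `maf_range` and Gaussian-copula LD within adjacent blocks. Planted
#' pathological columns emulate the artifacts the filtering cascade must
#' handle: near-monomorphic columns (non-modal fraction below 2%), columns
#' with missing rate at least `missing_rate_high`, and exact duplicates of a
#' partner column. Behavioral covariates are drawn with positive co-use
#' coupling; the ex-smoker outcome follows a logistic model combining the
#' behavioral effects and the planted per-allele genetic effects, anchored
#' at `baseline_prevalence`. `n_incomplete_pheno` participants get one
#' regression covariate blanked. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `phenotypes`
#'   (a `phenotype_table`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_snvs
  ids <- sprintf("P%04d", seq_len(n))
  meta <- snv_metadata_frame(p)

  n_special <- spec$n_low_variation + spec$n_high_missing + spec$n_duplicate
  role <- rep("ordinary", p)
  special_idx <- if (n_special > 0) sample.int(p, n_special) else integer(0)
  role[special_idx[seq_len(spec$n_low_variation)]] <- "low_variation"
  role[special_idx[spec$n_low_variation + seq_len(spec$n_high_missing)]] <-
    "high_missing"
  role[special_idx[spec$n_low_variation + spec$n_high_missing +
                   seq_len(spec$n_duplicate)]] <- "duplicate"

  mafs <- runif(p, spec$maf_range[1], spec$maf_range[2])
  mafs[role == "low_variation"] <- runif(sum(role == "low_variation"),
                                         0, 0.2 / n)
  dos <- draw_genotypes(n, mafs, spec$ld_block_size, spec$ld_rho)

  ordinary <- which(role == "ordinary")
  for (j in which(role == "duplicate"))
    dos[, j] <- dos[, sample(ordinary, 1)]
  for (j in which(role == "high_missing")) {
    k <- max(ceiling(n * spec$missing_rate_high), ceiling(n * 0.05))
    dos[sample.int(n, k), j] <- NA
  }

  # behavioral covariates with positive co-use coupling (shared latent)
  u <- rnorm(n)
  lat <- function(pr) {
    z <- 0.45 * u + sqrt(1 - 0.45^2) * rnorm(n)
    z < qnorm(pr)
  }
  marijuana <- lat(0.36)
  cocaine <- lat(0.19)
  hazard <- lat(0.15)
  audit <- ifelse(hazard, pmin(8 + rpois(n, 6), 40), pmin(rpois(n, 3), 7))
  gad7 <- pmin(pmax(round(7.3 + 0.8 * u + rnorm(n, 0, 5.7)), 0), 21)

  eff <- spec$behavioral_effects
  eta <- qlogis(spec$baseline_prevalence) +
    eff[["hazardous_alcohol"]] * (hazard - mean(hazard)) +
    eff[["marijuana_30d"]] * (marijuana - mean(marijuana)) +
    eff[["cocaine_30d"]] * (cocaine - mean(cocaine)) +
    eff[["gad7"]] * (gad7 - mean(gad7))
  if (length(spec$causal_effects)) {
    cidx <- causal_indices(spec$causal_effects, meta$id)
    for (k in seq_along(cidx)) {
      g <- dos[, cidx[k]]
      g[is.na(g)] <- 0
      eta <- eta + spec$causal_effects[k] * (g - mean(g))
    }
  }
  ex_smoker <- rbinom(n, 1, plogis(eta)) == 1
  outcome <- ifelse(ex_smoker, "ex_smoker", "smoker")

  age <- round(rnorm(n, 53.3, 9.9), 1)
  gender <- sample(c("male", "female", "transgender"), n, TRUE,
                   prob = c(0.495, 0.495, 0.01))
  race <- sample(c("black", "white", "other"), n, TRUE,
                 prob = c(0.763, 0.041, 0.196))
  latino <- runif(n) < 0.235
  education <- sample(EDUCATION_LEVELS, n, TRUE,
                      prob = c(0.382, 0.278, 0.20, 0.14))
  cesd <- pmin(pmax(round(rnorm(n, 20.7, 12.2)), 0), 60)

  pheno <- data.frame(sample_id = ids, outcome = outcome, age = age,
                      gender = gender, race = race, latino = latino,
                      education = education, audit_score = audit,
                      marijuana_30d = marijuana, cocaine_30d = cocaine,
                      cesd = cesd, gad7 = gad7, stringsAsFactors = FALSE)
  if (spec$n_incomplete_pheno > 0) {
    blank <- sample.int(n, spec$n_incomplete_pheno)
    cols <- sample(c("audit_score", "marijuana_30d", "cocaine_30d", "gad7"),
                   spec$n_incomplete_pheno, TRUE)
    for (k in seq_along(blank)) pheno[blank[k], cols[k]] <- NA
  }

  rownames(dos) <- ids
  list(genotypes = genotype_matrix(dos, meta),
       phenotypes = validate_phenotypes(pheno))
}

causal_indices <- function(causal_effects, snv_ids) {
  nm <- names(causal_effects)
  if (is.null(nm) || any(nm == "")) stop("causal_effects must be named")
  num <- suppressWarnings(as.integer(nm))
  idx <- ifelse(is.na(num), match(nm, snv_ids), num)
  if (anyNA(idx)) stop("unknown causal SNV: ",
                       paste(nm[is.na(idx)], collapse = ", "))
  idx
}

# deterministic assignment helper: value vector laid out by explicit counts
fill_by_counts <- function(values, counts) {
  rep(values, times = counts)
}

#' Deterministic study-mirror fixture
#'
#' Builds a cohort whose accounting exactly reproduces the study's printed
#' margins by construction (the counts are specification, not simulation):
#' 194 participants (142 current/recent smokers, 52 ex-smokers); behavioral
#' 2x2 margins of 61/139 vs 9/52 (marijuana), 35/139 vs 1/52 (cocaine),
#' 25/131 vs 2/48 (hazardous alcohol, AUDIT >= 8), 72/140 vs 24/52 (male);
#' exactly 37 participants missing at least one regression covariate (157
#' complete cases); and a 759-SNV panel in which, over the complete-case
#' subjects, exactly 124 SNVs fail the 2% variation filter, exactly 458 of
#' the remainder have a missing rate of at least 5%, and exactly 21 of the
#' remaining 177 duplicate another column's genotype profile, leaving 156
#' regression-ready SNVs. Continuous covariates and genotype draws are
#' seeded and deterministic; one SLC25A21 column carries a planted
#' ex-smoker-enriched alternate allele so the end-to-end report surface is
#' non-trivial.
#'
#' @param seed integer seed for the stochastic filler (default 194).
#' @return list with `genotypes` and `phenotypes`, as [generate_cohort()].
#' @export
paper_mirror_fixture <- function(seed = 194L) {
  set.seed(seed)
  n <- 194L
  n_smk <- 142L
  ids <- sprintf("P%04d", seq_len(n))
  outcome <- c(rep("smoker", n_smk), rep("ex_smoker", n - n_smk))
  smk <- seq_len(n_smk)
  exs <- (n_smk + 1L):n

  pheno <- data.frame(sample_id = ids, outcome = outcome,
                      age = NA_real_, gender = NA_character_,
                      race = NA_character_, latino = NA,
                      education = NA_character_, audit_score = NA_integer_,
                      marijuana_30d = NA, cocaine_30d = NA,
                      cesd = NA_integer_, gad7 = NA_integer_,
                      stringsAsFactors = FALSE)

  # regression-covariate missingness: 37 distinct incomplete participants
  audit_na <- c(smk[1:11], exs[1:4])
  mj_na <- smk[12:14]
  coc_na <- smk[15:17]
  gad_na <- smk[18:33]

  # hazardous alcohol: 25/131 smokers, 2/48 ex-smokers
  audit_ok_smk <- setdiff(smk, audit_na)     # 131
  audit_ok_exs <- setdiff(exs, audit_na)     # 48
  pheno$audit_score[c(audit_ok_smk[1:25], audit_ok_exs[1:2])] <- 12L
  pheno$audit_score[c(audit_ok_smk[26:131], audit_ok_exs[3:48])] <- 2L

  # marijuana: 61/139 vs 9/52; cocaine: 35/139 vs 1/52
  mj_ok_smk <- setdiff(smk, mj_na)
  pheno$marijuana_30d[mj_ok_smk] <- fill_by_counts(c(TRUE, FALSE), c(61, 78))
  pheno$marijuana_30d[exs] <- fill_by_counts(c(TRUE, FALSE), c(9, 43))
  coc_ok_smk <- setdiff(smk, coc_na)
  pheno$cocaine_30d[coc_ok_smk] <- fill_by_counts(c(TRUE, FALSE), c(35, 104))
  pheno$cocaine_30d[exs] <- fill_by_counts(c(TRUE, FALSE), c(1, 51))

  # gender 72/140 male vs 24/52; two smokers undeclared
  gender_na <- smk[141:142]
  pheno$gender[smk[1:140]] <- fill_by_counts(c("male", "female"), c(72, 68))
  pheno$gender[exs] <- fill_by_counts(c("male", "female"), c(24, 28))
  pheno$gender[gender_na] <- NA
  # race: 8 white / 110 black among smokers, 0/38 among ex-smokers
  pheno$race[smk] <- fill_by_counts(c("white", "black", "other"),
                                    c(8, 110, 24))
  pheno$race[exs] <- fill_by_counts(c("black", "other"), c(38, 14))
  # Latino/a 33/140 vs 12/52
  pheno$latino[smk[1:140]] <- fill_by_counts(c(TRUE, FALSE), c(33, 107))
  pheno$latino[exs] <- fill_by_counts(c(TRUE, FALSE), c(12, 40))
  pheno$latino[smk[141:142]] <- NA
  # education
  pheno$education[smk] <- fill_by_counts(EDUCATION_LEVELS, c(57, 37, 35, 13))
  pheno$education[exs] <- fill_by_counts(EDUCATION_LEVELS, c(17, 17, 10, 8))

  # continuous scores: seeded draws near the reported group moments
  pheno$age <- round(c(rnorm(n_smk, 52.5, 10.0), rnorm(n - n_smk, 55.2, 9.6)), 1)
  pheno$cesd <- pmin(pmax(round(c(rnorm(n_smk, 21.2, 12.2),
                                  rnorm(n - n_smk, 19.2, 12.4))), 0), 60)
  pheno$gad7 <- pmin(pmax(round(c(rnorm(n_smk, 8.1, 6.3),
                                  rnorm(n - n_smk, 5.3, 5.3))), 0), 21)

  pheno$audit_score[audit_na] <- NA
  pheno$marijuana_30d[mj_na] <- NA
  pheno$cocaine_30d[coc_na] <- NA
  pheno$gad7[gad_na] <- NA

  pheno <- validate_phenotypes(pheno)
  cc <- complete_case(pheno)                 # the 157 complete cases
  cc_idx <- match(cc, ids)
  n_cc <- length(cc_idx)

  # --- genotype panel: 124 low-variation | 458 high-missing | 156 distinct
  #     retained | 21 duplicates, all relative to the complete-case samples
  p <- 759L
  meta <- snv_metadata_frame(p)
  dos <- matrix(0, n, p, dimnames = list(ids, meta$id))
  low_idx <- 1:124
  hm_idx <- 125:582
  keep_idx <- 583:738
  dup_idx <- 739:759

  hw_column <- function(maf, rows) (runif(length(rows)) < maf) +
                                   (runif(length(rows)) < maf)
  # guarantee the variation filter outcome over complete cases
  force_min_nonmodal <- function(x, k = 5L) {
    cnt <- tabulate(x + 1, nbins = 3)
    modal <- which.max(cnt) - 1
    nm <- sum(x != modal)
    if (nm < k) x[which(x == modal)[seq_len(k - nm)]] <- ifelse(modal == 0, 1, 0)
    x
  }

  for (j in low_idx) {
    col <- numeric(n)
    col[cc_idx[j %% n_cc + 1]] <- 1          # one heterozygote: 1/157 < 2%
    dos[, j] <- col
  }
  for (j in hm_idx) {
    col <- hw_column(runif(1, 0.15, 0.45), seq_len(n))
    col[cc_idx[((j * 7L + seq_len(8L)) %% n_cc) + 1L]] <- NA  # 8/157 >= 5%
    obs <- cc_idx[!is.na(col[cc_idx])]
    col[obs] <- force_min_nonmodal(col[obs])  # keeps it past the 2% filter
    dos[, j] <- col
  }
  planted <- keep_idx[which(meta$gene[keep_idx] == "SLC25A21")[1]]
  meta$pos[planted] <- 37148248L
  meta$ref[planted] <- "T"; meta$alt[planted] <- "C"
  for (j in keep_idx) {
    repeat {
      col <- if (j == planted) {
        ifelse(outcome == "ex_smoker",
               hw_column(0.40, seq_len(n)), hw_column(0.18, seq_len(n)))
      } else hw_column(runif(1, 0.1, 0.45), seq_len(n))
      col[cc_idx] <- force_min_nonmodal(col[cc_idx])
      key <- paste(col[cc_idx], collapse = "")
      prev <- if (j > keep_idx[1])
        apply(dos[cc_idx, keep_idx[1]:(j - 1), drop = FALSE], 2,
              paste, collapse = "")
      else character(0)
      if (!key %in% prev) break              # retained profiles are distinct
    }
    dos[, j] <- col
  }
  for (k in seq_along(dup_idx)) {
    partner <- keep_idx[k]
    col <- dos[, partner]
    off_cc <- setdiff(seq_len(n), cc_idx)
    col[off_cc[k %% length(off_cc) + 1]] <-
      (col[off_cc[k %% length(off_cc) + 1]] + 1) %% 3  # differ off the cc set
    dos[, dup_idx[k]] <- col
  }

  list(genotypes = genotype_matrix(dos, meta), phenotypes = pheno)
}
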