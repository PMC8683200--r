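make_matrix <- function(cols) {
  ids <- sprintf("s%02d", seq_along(cols))
  dos <- do.call(cbind, cols)
  rownames(dos) <- sprintf("P%03d", seq_len(nrow(dos)))
  meta <- data.frame(id = ids, chrom = "1", pos = seq_along(cols),
                     ref = "A", alt = "G", gene = "other",
                     stringsAsFactors = FALSE)
  genotype_matrix(dos, meta)
}

test_that("variation filter uses the non-modal fraction of non-missing calls", {
  n <- 194
  allzero <- rep(0, n)
  one_het <- c(1, rep(0, n - 1))            # 1/194 = 0.52% < 2%
  five_nm <- c(rep(1, 5), rep(0, n - 5))    # 5/194 = 2.58% >= 2%
  allmiss <- rep(NA_real_, n)
  G <- make_matrix(list(allzero, one_het, five_nm, allmiss))
  res <- variation_filter(G, 0.02)
  expect_setequal(res$removed, c("s01", "s02", "s04"))
  expect_identical(res$retained, "s03")
})

test_that("missingness filter applies the >= 5% rule", {
  n <- 194
  base <- rep(c(0, 1, 2), length.out = n)
  with_k_missing <- function(k) { x <- base; x[seq_len(k)] <- NA; x }
  G <- make_matrix(list(base, with_k_missing(10), with_k_missing(9)))
  res <- missingness_filter(G, 0.05)
  expect_identical(res$removed, "s02")     # 10/194 = 5.15%
  expect_setequal(res$retained, c("s01", "s03"))  # 9/194 = 4.64%
})

test_that("duplicate-profile collapse keeps one representative per class", {
  x <- rep(c(0, 1, 2, 1), 5)
  y <- rep(c(2, 0, 1, 1), 5)
  G <- make_matrix(list(x, x, x, y))
  res <- collapse_identical(G)
  expect_identical(res$removed, c("s02", "s03"))
  expect_setequal(res$retained, c("s01", "s04"))

  # identity is scoped to the given samples: equal on the subset, different
  # on an excluded sample
  x2 <- x; x2[1] <- 2
  G2 <- make_matrix(list(x, x2))
  sub <- rownames(G2$dosage)[-1]
  expect_length(collapse_identical(G2, samples = sub)$removed, 1)
  expect_length(collapse_identical(G2)$removed, 0)
})

test_that("complete-case filter drops any-missing participants", {
  ph <- tiny_phenotypes(6)
  ph$audit_score[2] <- NA
  ph$gad7[5] <- NA
  ph <- validate_phenotypes(ph)
  kept <- complete_case(ph)
  expect_setequal(kept, ph$sample_id[-c(2, 5)])
  expect_identical(complete_case(ph, character(0)), ph$sample_id)
  expect_error(complete_case(ph, "not_a_covariate"), "unknown covariate")
})

test_that("design matrix codes dosages additively and imputes within support", {
  cohort <- generate_cohort(cohort_spec(
    n_samples = 60, n_snvs = 20, n_low_variation = 0, n_high_missing = 3,
    n_duplicate = 0, n_incomplete_pheno = 0, seed = 3))
  fp <- filter_pipeline(cohort$genotypes, cohort$phenotypes)
  X <- fp$design$X
  expect_false(anyNA(X))
  snv_cols <- X[, -(1:4)]
  expect_true(all(snv_cols %in% c(0, 1, 2)))
  expect_identical(colnames(X)[1:4],
                   c("hazardous_alcohol", "marijuana_30d", "cocaine_30d",
                     "anxiety_gad7"))
  expect_setequal(unique(fp$design$y), c(0, 1))
})

test_that("flipping the positive outcome negates unpenalized coefficients", {
  cohort <- generate_cohort(cohort_spec(
    n_samples = 120, n_snvs = 6, n_low_variation = 0, n_high_missing = 0,
    n_duplicate = 0, n_incomplete_pheno = 0, seed = 8))
  f1 <- filter_pipeline(cohort$genotypes, cohort$phenotypes,
                        outcome_positive = "ex_smoker")
  f2 <- filter_pipeline(cohort$genotypes, cohort$phenotypes,
                        outcome_positive = "smoker")
  m1 <- logistic_mle(f1$design$X, f1$design$y)
  m2 <- logistic_mle(f2$design$X, f2$design$y)
  expect_equal(m1$coefs, -m2$coefs, tolerance = 1e-6)
})

test_that("filter accounting identity holds on random cohorts", {
  for (seed in 1:4) {
    spec <- cohort_spec(n_samples = 50, n_snvs = 40,
                        n_low_variation = sample(0:5, 1),
                        n_high_missing = sample(0:8, 1),
                        n_duplicate = sample(0:4, 1),
                        n_incomplete_pheno = sample(0:6, 1), seed = seed)
    cohort <- generate_cohort(spec)
    r <- filter_pipeline(cohort$genotypes, cohort$phenotypes)$report
    expect_identical(
      r$n_retained_snvs,
      r$n_input_snvs - r$n_low_variation - r$n_high_missing -
        r$n_duplicate_collapsed)
    expect_lte(r$n_complete_case, r$n_input_samples)
    # stages are disjoint
    all_removed <- unlist(r$removed_ids)
    expect_identical(anyDuplicated(all_removed), 0L)
  }
})

test_that("the filtering cascade is idempotent", {
  cohort <- generate_cohort(cohort_spec(
    n_samples = 60, n_snvs = 30, n_low_variation = 4, n_high_missing = 5,
    n_duplicate = 3, n_incomplete_pheno = 5, seed = 13))
  r1 <- filter_pipeline(cohort$genotypes, cohort$phenotypes)$report
  keep <- r1$retained_snvs
  G2 <- cohort$genotypes
  G2$dosage <- G2$dosage[, keep, drop = FALSE]
  G2$snv_meta <- G2$snv_meta[match(keep, G2$snv_meta$id), ]
  r2 <- filter_pipeline(G2, cohort$phenotypes)$report
  expect_identical(r2$n_low_variation, 0L)
  expect_identical(r2$n_high_missing, 0L)
  expect_identical(r2$n_duplicate_collapsed, 0L)
  expect_identical(r2$n_retained_snvs, r1$n_retained_snvs)
})
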