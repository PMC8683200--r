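test_that("cohort generation is fully reproducible from the seed", {
  spec <- cohort_spec(n_samples = 40, n_snvs = 25, n_low_variation = 3,
                      n_high_missing = 4, n_duplicate = 2,
                      n_incomplete_pheno = 5, seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
  expect_identical(as.data.frame(c1$phenotypes), as.data.frame(c2$phenotypes))
  expect_identical(sum(is.na(c1$genotypes$dosage)),
                   sum(is.na(c2$genotypes$dosage)))
})

test_that("infeasible cohort specifications are rejected", {
  expect_error(cohort_spec(n_snvs = 10, n_low_variation = 5,
                           n_high_missing = 5, n_duplicate = 2), "fewer")
  expect_error(cohort_spec(baseline_prevalence = 0), "prevalence")
  expect_error(cohort_spec(missing_rate_high = 0.01), ">= 0.05")
})

test_that("genotype marginals follow Hardy-Weinberg at fixed allele frequency", {
  spec <- cohort_spec(n_samples = 5000, n_snvs = 6, maf_range = c(0.3, 0.3),
                      n_low_variation = 0, n_high_missing = 0,
                      n_duplicate = 0, n_incomplete_pheno = 0, ld_rho = 0.5,
                      seed = 77)
  G <- generate_cohort(spec)$genotypes$dosage
  for (j in seq_len(ncol(G))) {
    freq <- tabulate(G[, j] + 1, nbins = 3) / nrow(G)
    expected <- c(0.49, 0.42, 0.09)      # (1-f)^2, 2f(1-f), f^2 at f = 0.3
    expect_true(all(abs(freq - expected) < 4 * sqrt(expected / nrow(G)) + 0.01))
  }
})

test_that("within-block dosage correlation increases with the LD parameter", {
  cor_at <- function(rho) {
    spec <- cohort_spec(n_samples = 3000, n_snvs = 10,
                        maf_range = c(0.3, 0.3), n_low_variation = 0,
                        n_high_missing = 0, n_duplicate = 0,
                        n_incomplete_pheno = 0, ld_block_size = 5,
                        ld_rho = rho, seed = 55)
    G <- generate_cohort(spec)$genotypes$dosage
    mean(c(cor(G[, 1], G[, 2]), cor(G[, 3], G[, 4]), cor(G[, 6], G[, 7])))
  }
  r_low <- cor_at(0.1); r_mid <- cor_at(0.5); r_high <- cor_at(0.9)
  expect_lt(r_low, r_mid)
  expect_lt(r_mid, r_high)
  expect_lt(abs(cor_at(0)), 0.06)
})

test_that("null cohorts show no genotype-outcome association", {
  spec <- cohort_spec(n_samples = 5000, n_snvs = 8, n_low_variation = 0,
                      n_high_missing = 0, n_duplicate = 0,
                      n_incomplete_pheno = 0,
                      behavioral_effects = c(hazardous_alcohol = 0,
                                             marijuana_30d = 0,
                                             cocaine_30d = 0, gad7 = 0),
                      seed = 123)
  cohort <- generate_cohort(spec)
  y <- as.numeric(cohort$phenotypes$outcome == "ex_smoker")
  for (j in 1:4) {
    f <- glm(y ~ cohort$genotypes$dosage[, j], family = binomial)
    z <- summary(f)$coefficients[2, 3]
    expect_lt(abs(z), 3.5)               # within a null band
  }
})

test_that("planted per-allele effects are recovered at large n", {
  spec <- cohort_spec(n_samples = 20000, n_snvs = 10, n_low_variation = 0,
                      n_high_missing = 0, n_duplicate = 0,
                      n_incomplete_pheno = 0, ld_rho = 0,
                      behavioral_effects = c(hazardous_alcohol = 0,
                                             marijuana_30d = 0,
                                             cocaine_30d = 0, gad7 = 0),
                      causal_effects = c(snv0004 = log(2)), seed = 2024)
  cohort <- generate_cohort(spec)
  y <- as.numeric(cohort$phenotypes$outcome == "ex_smoker")
  f <- glm(y ~ cohort$genotypes$dosage[, 4], family = binomial)
  expect_equal(unname(coef(f)[2]), log(2), tolerance = 0.05 / log(2))
})

test_that("the mirror fixture reproduces the study accounting deterministically", {
  cohort <- mirror_cohort()
  again <- paper_mirror_fixture()
  expect_identical(cohort$genotypes$dosage, again$genotypes$dosage)
  ph <- cohort$phenotypes
  expect_identical(nrow(ph), 194L)
  expect_identical(sum(ph$outcome == "smoker"), 142L)
  smk <- ph$outcome == "smoker"
  expect_identical(sum(ph$marijuana_30d[smk], na.rm = TRUE), 61L)
  expect_identical(sum(!is.na(ph$marijuana_30d[smk])), 139L)
  expect_identical(sum(ph$cocaine_30d[!smk], na.rm = TRUE), 1L)
  expect_identical(sum(ph$audit_score[smk] >= 8, na.rm = TRUE), 25L)
  expect_identical(sum(!is.na(ph$audit_score[!smk])), 48L)
  expect_identical(sum(ph$gender[smk] == "male", na.rm = TRUE), 72L)
  incomplete <- is.na(ph$audit_score) | is.na(ph$marijuana_30d) |
    is.na(ph$cocaine_30d) | is.na(ph$gad7)
  expect_identical(sum(incomplete), 37L)
})
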