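test_that("truncated-Gaussian p-values honor boundaries and the normal limit", {
  expect_equal(truncated_gaussian_pvalue(0.5, 1, 0.5, 2, two_sided = FALSE), 1)
  expect_equal(truncated_gaussian_pvalue(2, 1, 0.5, 2, two_sided = FALSE), 0)
  p <- truncated_gaussian_pvalue(1.96, 1, -Inf, Inf, two_sided = FALSE)
  expect_equal(p, pnorm(1.96, lower.tail = FALSE), tolerance = 1e-9)
  # unbounded two-sided equals the classical normal p-value
  p2 <- truncated_gaussian_pvalue(1.96, 1, -Inf, Inf)
  expect_equal(p2, 2 * pnorm(1.96, lower.tail = FALSE), tolerance = 1e-9)
  expect_error(truncated_gaussian_pvalue(3, 1, 0, 2), "outside truncation")
  # extreme tails stay finite and ordered
  p_far <- truncated_gaussian_pvalue(12, 1, 10, 20, two_sided = FALSE)
  expect_true(is.finite(p_far) && p_far > 0 && p_far < 1)
})

test_that("planted strong effects are selected with small selective p-values", {
  hits <- 0; selected <- 0
  nrep <- 60
  for (r in seq_len(nrep)) {
    set.seed(3000 + r)
    X <- matrix(rbinom(500 * 10, 2, 0.3), 500, 10,
                dimnames = list(NULL, paste0("s", 1:10)))
    y <- rbinom(500, 1, plogis(-1 + 1.5 * X[, 1]))
    fit <- fit_enet_logistic(X, y, 1, 0.03)
    si <- selective_inference(X, y, 0.03, fit = fit)
    if ("s1" %in% si$name) {
      selected <- selected + 1
      if (si$p_selective[si$name == "s1"] < 0.05) hits <- hits + 1
    }
  }
  expect_gte(selected, 0.95 * nrep)
  expect_gte(hits / selected, 0.9)
})

test_that("selective p-values are monotone in the planted effect size", {
  ps <- vapply(c(0.6, 0.9, 1.2), function(b) {
    set.seed(33)
    X <- matrix(rbinom(157 * 5, 2, 0.3), 157, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
    y <- rbinom(157, 1, plogis(-1 + b * X[, 1]))
    fit <- fit_enet_logistic(X, y, 1, 0.05)
    si <- selective_inference(X, y, 0.05, fit = fit)
    si$p_selective[si$name == "s1"]
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("with one predictor and vanishing penalty the selective p-value
           approaches twice the classical two-sided p", {
  # conditioning on the selection sign retains half the reference mass as
  # lambda -> 0, so the two-sided selective p tends to 2x the Wald p
  set.seed(9)
  n <- 1000
  x <- matrix(rbinom(n, 2, 0.3), ncol = 1, dimnames = list(NULL, "g"))
  y <- rbinom(n, 1, plogis(-0.5 + 0.25 * x))
  si <- selective_inference(x, y, lambda = 1e-3)
  wald <- summary(glm(y ~ x, family = binomial))$coefficients[2, 4]
  expect_equal(si$p_selective, min(1, 2 * wald), tolerance = 0.15)
  expect_equal(si$estimate, unname(coef(glm(y ~ x, family = binomial))[2]),
               tolerance = 1e-3)
})

test_that("empty active sets and collinear designs are reported, not hidden", {
  d <- sim_logistic(50, 3, rep(0, 3), seed = 11)
  lam_hi <- lambda_path(d$X, d$y, 1, n_lambda = 2)[1]
  expect_warning(res <- selective_inference(d$X, d$y, lam_hi), "empty active")
  expect_identical(nrow(res), 0L)

  set.seed(12)
  x <- rnorm(60)
  X <- cbind(a = x, b = x + rnorm(60, sd = 1e-9), c = rnorm(60))
  y <- rbinom(60, 1, plogis(2 * x))
  # force both collinear columns active by exempting them from the penalty
  fit <- fit_enet_logistic(X, y, 1, 0.05, penalty_factors = c(0, 0, 1),
                           max_outer = 50)
  expect_error(selective_inference(X, y, 0.05, fit = fit), "ill-conditioned")
})

test_that("the adjusted-OR report is ordered and labelled from SNV metadata", {
  fp <- mirror_design()
  cohort <- mirror_cohort()
  set.seed(2)
  cv <- grid_search(fp$design$X, fp$design$y, alphas = 1, n_lambda = 40)
  t2 <- table2_report(fp$design, cv, snv_meta = cohort$genotypes$snv_meta)
  expect_gt(nrow(t2), 0)
  expect_true(all(t2$p_selective >= 0 & t2$p_selective <= 1))
  expect_true(all(is.finite(t2$or_adj)))
  snv_rows <- grepl("Chr\\.", t2$factor)
  if (any(snv_rows)) {
    expect_match(t2$factor[snv_rows][1], "pos\\.")
    # clinical covariates, when selected, come first
    if (any(!snv_rows))
      expect_lt(max(which(!snv_rows)), min(which(snv_rows)))
  }
})
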