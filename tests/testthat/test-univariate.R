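test_that("odds ratio and Woolf CI reproduce the published 2x2 examples", {
  mj <- odds_ratio_ci(list(a = 61, b = 78, c = 9, d = 43))
  expect_equal(mj$or, 3.73, tolerance = 0.01 / 3.73)
  expect_equal(mj$ci_low, 1.69, tolerance = 0.01)
  expect_equal(mj$ci_high, 8.26, tolerance = 0.01)
  coc <- odds_ratio_ci(list(a = 35, b = 104, c = 1, d = 51))
  expect_equal(coc$or, 17.2, tolerance = 0.05 / 17.2)
  # symmetric table gives OR exactly 1 for any k
  for (k in c(1, 7, 30))
    expect_identical(odds_ratio_ci(list(a = k, b = k, c = k, d = k))$or, 1)
})

test_that("zero cells flag infinite/undefined ORs instead of correcting", {
  inf_or <- odds_ratio_ci(list(a = 5, b = 0, c = 2, d = 8))
  expect_identical(inf_or$flag, "infinite")
  expect_true(is.infinite(inf_or$or))
  und <- odds_ratio_ci(list(a = 5, b = 0, c = 0, d = 8))
  expect_identical(und$flag, "undefined")
  # Haldane correction only when requested
  hc <- odds_ratio_ci(list(a = 5, b = 0, c = 2, d = 8), haldane = TRUE)
  expect_true(is.finite(hc$or))
})

test_that("OR equivariance and group-swap symmetry hold", {
  set.seed(4)
  for (i in 1:10) {
    tb <- random_contingency()
    o1 <- odds_ratio_ci(tb)$or
    o2 <- odds_ratio_ci(list(a = tb$b, b = tb$a, c = tb$d, d = tb$c))$or
    expect_equal(o1 * o2, 1, tolerance = 1e-12)
    swapped <- list(a = tb$c, b = tb$d, c = tb$a, d = tb$b)
    expect_equal(odds_ratio_ci(swapped)$or, 1 / o1, tolerance = 1e-12)
    expect_equal(chi_square_test(swapped), chi_square_test(tb),
                 tolerance = 1e-12)
    expect_equal(fisher_exact_test(swapped), fisher_exact_test(tb),
                 tolerance = 1e-12)
  }
})

test_that("chi-square matches the closed 2x2 form and handles degeneracy", {
  set.seed(11)
  for (i in 1:10) {
    tb <- random_contingency()
    n <- tb$a + tb$b + tb$c + tb$d
    stat <- n * (tb$a * tb$d - tb$b * tb$c)^2 /
      ((tb$a + tb$b) * (tb$c + tb$d) * (tb$a + tb$c) * (tb$b + tb$d))
    expect_equal(chi_square_test(tb), pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # proportional rows: perfectly independent
  expect_equal(chi_square_test(list(a = 10, b = 20, c = 5, d = 10)), 1)
  expect_error(chi_square_test(list(a = 0, b = 0, c = 3, d = 4)),
               "zero marginal")
})

test_that("Fisher exact equals hypergeometric enumeration for small tables", {
  enumerate_fisher <- function(tb) {
    m <- tb$a + tb$c; nn <- tb$b + tb$d; k <- tb$a + tb$b
    lo <- max(0, k - nn); hi <- min(k, m)
    probs <- dhyper(lo:hi, m, nn, k)
    p_obs <- dhyper(tb$a, m, nn, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  expect_equal(fisher_exact_test(list(a = 1, b = 0, c = 0, d = 1)), 1)
  expect_equal(fisher_exact_test(list(a = 0, b = 0, c = 3, d = 4)), 1)
  set.seed(21)
  for (i in 1:20) {
    tb <- random_contingency(max_cell = 8)   # total N <= 32
    expect_equal(fisher_exact_test(tb), enumerate_fisher(tb),
                 tolerance = 1e-10)
  }
})

test_that("two-group comparisons honor their symmetry identities", {
  g <- rep(c("smoker", "ex_smoker"), each = 3)
  r <- two_group_continuous(c(1, 2, 3, 1, 2, 3), g, "t_test")
  expect_equal(r$p_value, 1)
  expect_equal(unname(r$means), c(2, 2))
  rw <- two_group_continuous(c(1, 2, 3, 1, 2, 3), g, "mann_whitney")
  expect_equal(rw$p_value, 1, tolerance = 1e-9)
  expect_error(two_group_continuous(c(1, 2, 3, 4), rep(c("a", "b"), c(3, 1))),
               ">= 2")
})

test_that("contingency builder derives exposures and handles missingness", {
  ph <- tiny_phenotypes(6)
  ph$audit_score <- c(7L, 8L, NA, 3L, 9L, 2L)
  ph <- validate_phenotypes(ph)
  tb <- build_contingency(ph, "hazardous_alcohol")
  # AUDIT >= 8 boundary: scores {7,8} -> exactly one exposed
  expect_equal(tb$a + tb$c, 2)
  expect_equal(tb$a + tb$b + tb$c + tb$d, 5)  # NA dropped from this table
  ph2 <- tiny_phenotypes(4)
  ph2$marijuana_30d <- rep(NA, 4)
  ph2 <- validate_phenotypes(ph2)
  expect_error(build_contingency(ph2, "marijuana_30d"), "empty contingency")
  expect_error(build_contingency(ph, "age"), "not boolean")
})

test_that("the univariate table reproduces the mirror cohort's key rows", {
  pheno <- mirror_cohort()$phenotypes
  t1 <- table1_report(pheno)
  expect_setequal(
    t1$variable,
    c("age", "male_gender", "race_white_vs_black", "latino", "education",
      "hazardous_alcohol", "marijuana_30d", "cocaine_30d", "depression_cesd",
      "anxiety_gad7"))
  mj <- t1[t1$variable == "marijuana_30d", ]
  expect_equal(mj$or_point, 3.73, tolerance = 0.01 / 3.73)
  expect_equal(mj$n_smokers, 139)
  expect_equal(mj$n_exsmokers, 52)
  gen <- t1[t1$variable == "male_gender", ]
  expect_equal(gen$or_point, 1.24, tolerance = 0.01 / 1.24)
  expect_equal(gen$n_smokers, 140)
  expect_true(all(t1$p_value >= 0 & t1$p_value <= 1))
  expect_error(table1_report(pheno[0, ]), "empty")
})
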