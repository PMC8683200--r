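#' 2x2 contingency table for a behavioral exposure vs smoking status
#'
#' Orientation: `a` = exposed among current/recent smokers, `b` = unexposed
#' among smokers, `c` = exposed among ex-smokers, `d` = unexposed among
#' ex-smokers, so that OR > 1 means the exposure is associated with current
#' smoking. Participants with a missing exposure are dropped from this table
#' only, so denominators may differ across exposures.
#'
#' @param pheno a `phenotype_table`.
#' @param exposure covariate name: one of `"hazardous_alcohol"` (derived as
#'   AUDIT score >= `audit_cutoff`), `"marijuana_30d"`, `"cocaine_30d"`,
#'   `"male"`, `"latino"`, or any logical column of `pheno`.
#' @param audit_cutoff AUDIT threshold defining hazardous alcohol use
#'   (default 8).
#' @return A `contingency_2x2` list with counts `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(pheno, exposure, audit_cutoff = 8) {
  x <- derive_exposure(pheno, exposure, audit_cutoff)
  smoker <- pheno$outcome == "smoker"
  keep <- !is.na(x)
  if (!any(keep)) stop("empty contingency table: all exposures missing")
  x <- x[keep]; smoker <- smoker[keep]
  tab <- list(a = sum(smoker & x), b = sum(smoker & !x),
              c = sum(!smoker & x), d = sum(!smoker & !x),
              exposure = exposure)
  class(tab) <- "contingency_2x2"
  tab
}

derive_exposure <- function(pheno, exposure, audit_cutoff = 8) {
  switch(exposure,
    hazardous_alcohol = pheno$audit_score >= audit_cutoff,
    male = ifelse(is.na(pheno$gender), NA, pheno$gender == "male"),
    {
      if (!exposure %in% names(pheno))
        stop("unknown exposure: ", exposure)
      x <- pheno[[exposure]]
      if (!is.logical(x))
        stop("exposure '", exposure,
             "' is not boolean and has no derivation rule")
      x
    })
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$c, tab$b, tab$d), nrow = 2,
         dimnames = list(group = c("smoker", "ex_smoker"),
                         exposed = c("yes", "no")))
}

#' Odds ratio with Woolf confidence interval
#'
#' Point estimate `(a*d)/(b*c)` with the Woolf log-OR interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. No continuity
#' correction is applied by default; zero cells yield infinite or undefined
#' estimates flagged in the result rather than silently corrected.
#'
#' @param tab a `contingency_2x2` from [build_contingency()] or a list with
#'   counts `a`, `b`, `c`, `d`.
#' @param level confidence level (default 0.95).
#' @param haldane if `TRUE`, add 0.5 to every cell (Haldane-Anscombe
#'   correction) before estimating. Off by default.
#' @return list with `or`, `ci_low`, `ci_high`, `flag`
#'   (`"ok"`, `"infinite"`, or `"undefined"`).
#' @export
odds_ratio_ci <- function(tab, level = 0.95, haldane = FALSE) {
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  z <- qnorm(1 - (1 - level) / 2)
  if (b == 0 && c == 0)
    return(list(or = NaN, ci_low = NaN, ci_high = NaN, flag = "undefined"))
  or <- (a * d) / (b * c)
  if (any(c(a, b, c, d) == 0)) {
    return(list(or = or, ci_low = if (or == 0) 0 else NaN,
                ci_high = if (is.infinite(or)) Inf else NaN,
                flag = "infinite"))
  }
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       flag = "ok")
}

#' Pearson chi-square test for a 2x2 table
#'
#' @param tab a `contingency_2x2`.
#' @param correction apply the Yates continuity correction (default `FALSE`).
#' @return two-sided p-value.
#' @export
chi_square_test <- function(tab, correction = FALSE) {
  m <- as_matrix_2x2(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square undefined: zero marginal")
  suppressWarnings(stats::chisq.test(m, correct = correction)$p.value)
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities (fixed margins) of
#' tables no more probable than the observed one. Degenerate margins give
#' p = 1.
#'
#' @param tab a `contingency_2x2`.
#' @export
fisher_exact_test <- function(tab) {
  m <- as_matrix_2x2(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Two-group comparison of a continuous covariate
#'
#' Student's t-test uses the pooled-variance form; the Mann-Whitney U test
#' uses mid-ranks for ties with the normal approximation.
#'
#' @param values numeric vector.
#' @param groups outcome labels, two levels (e.g. `"smoker"` /
#'   `"ex_smoker"`); missing values dropped pairwise.
#' @param method `"t_test"` or `"mann_whitney"`.
#' @return list with `p_value`, and per-group `mean` and `sd`.
#' @export
two_group_continuous <- function(values, groups,
                                 method = c("t_test", "mann_whitney")) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  lev <- unique(groups)
  if (length(lev) != 2) stop("need exactly two groups")
  x <- values[groups == lev[1]]; y <- values[groups == lev[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 non-missing values per group")
  p <- if (method == "t_test") {
    stats::t.test(x, y, var.equal = TRUE)$p.value
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  }
  res <- list(p_value = p,
              means = c(mean(x), mean(y)), sds = c(sd(x), sd(y)),
              n = c(length(x), length(y)))
  names(res$means) <- names(res$sds) <- names(res$n) <- lev
  res
}

expected_counts <- function(tab) {
  m <- as_matrix_2x2(tab)
  outer(rowSums(m), colSums(m)) / sum(m)
}

# test choice heuristics: Fisher exact when any expected cell < 5, else
# Pearson chi-square; pooled t when both groups look roughly normal
# (|skewness| < 1), else Mann-Whitney
choose_categorical_test <- function(tab) {
  if (any(expected_counts(tab) < 5)) "fisher_exact" else "chi_square"
}

skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

choose_continuous_test <- function(values, groups) {
  ok <- !is.na(values)
  sk <- tapply(values[ok], groups[ok], skewness)
  if (all(abs(sk) < 1)) "t_test" else "mann_whitney"
}

categorical_row <- function(pheno, variable, exposure, audit_cutoff = 8) {
  tab <- build_contingency(pheno, exposure, audit_cutoff)
  orci <- odds_ratio_ci(tab)
  test <- choose_categorical_test(tab)
  p <- if (test == "fisher_exact") fisher_exact_test(tab)
       else chi_square_test(tab)
  data.frame(variable = variable, test_used = test,
             or_point = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high,
             p_value = p,
             n_smokers = tab$a + tab$b, n_exsmokers = tab$c + tab$d,
             stringsAsFactors = FALSE)
}

continuous_row <- function(pheno, variable, column) {
  test <- choose_continuous_test(pheno[[column]], pheno$outcome)
  res <- two_group_continuous(pheno[[column]], pheno$outcome, test)
  data.frame(variable = variable, test_used = test,
             or_point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             p_value = res$p_value,
             n_smokers = res$n[["smoker"]], n_exsmokers = res$n[["ex_smoker"]],
             stringsAsFactors = FALSE)
}

#' Univariate characteristics table (smokers vs ex-smokers)
#'
#' One association result per cohort characteristic: age, male gender, race
#' (White vs Black among participants declaring one of the two), Latino/a
#' ethnicity, education (4 ordered levels), hazardous alcohol use
#' (AUDIT >= 8), past-30-day marijuana and cocaine use, depression (CESD-20)
#' and anxiety (GAD-7) scores. Categorical rows carry an odds ratio with a
#' Woolf 95% CI; test choice follows the expected-count / skewness
#' heuristics. Denominators reflect per-variable missingness.
#'
#' @param pheno a `phenotype_table`.
#' @param audit_cutoff AUDIT threshold for hazardous drinking (default 8).
#' @return data.frame of class `table1_report`, one row per characteristic.
#' @export
table1_report <- function(pheno, audit_cutoff = 8) {
  if (nrow(pheno) == 0) stop("empty phenotype table")
  if (!all(c("smoker", "ex_smoker") %in% pheno$outcome))
    stop("both outcome groups must be present")
  rows <- list(
    continuous_row(pheno, "age", "age"),
    categorical_row(pheno, "male_gender", "male"),
    race_row(pheno),
    categorical_row(pheno, "latino", "latino"),
    education_row(pheno),
    categorical_row(pheno, "hazardous_alcohol", "hazardous_alcohol",
                    audit_cutoff),
    categorical_row(pheno, "marijuana_30d", "marijuana_30d"),
    categorical_row(pheno, "cocaine_30d", "cocaine_30d"),
    continuous_row(pheno, "depression_cesd", "cesd"),
    continuous_row(pheno, "anxiety_gad7", "gad7"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("table1_report", "data.frame")
  out
}

# White vs Black among participants declaring one of those two categories
race_row <- function(pheno) {
  sub <- pheno[!is.na(pheno$race) & pheno$race %in% c("white", "black"), ]
  tab <- list(a = sum(sub$outcome == "smoker" & sub$race == "white"),
              b = sum(sub$outcome == "smoker" & sub$race == "black"),
              c = sum(sub$outcome == "ex_smoker" & sub$race == "white"),
              d = sum(sub$outcome == "ex_smoker" & sub$race == "black"))
  class(tab) <- "contingency_2x2"
  p <- fisher_exact_test(tab)
  data.frame(variable = "race_white_vs_black", test_used = "fisher_exact",
             or_point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             p_value = p, n_smokers = tab$a + tab$b,
             n_exsmokers = tab$c + tab$d, stringsAsFactors = FALSE)
}

education_row <- function(pheno) {
  keep <- !is.na(pheno$education)
  m <- table(pheno$education[keep], pheno$outcome[keep])
  exp_ok <- all(outer(rowSums(m), colSums(m)) / sum(m) >= 5)
  if (exp_ok) {
    p <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
    test <- "chi_square"
  } else {
    p <- stats::fisher.test(m)$p.value
    test <- "fisher_exact"
  }
  data.frame(variable = "education", test_used = test,
             or_point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             p_value = p,
             n_smokers = sum(keep & pheno$outcome == "smoker"),
             n_exsmokers = sum(keep & pheno$outcome == "ex_smoker"),
             stringsAsFactors = FALSE)
}
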