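#' Truncated-Gaussian p-value (polyhedral-lemma kernel)
#'
#' Survival-function ratio for an estimate known to lie in the truncation
#' interval `[v_minus, v_plus]` under a `N(null_mean, sd^2)` reference:
#' one-sided
#' `p = (S((t-m)/sd) - S((v+-m)/sd)) / (S((v--m)/sd) - S((v+-m)/sd))`
#' with `S` the standard normal survival function, computed via
#' log-survival differences so extreme tails stay accurate. The two-sided
#' value doubles the smaller tail and caps at 1.
#'
#' @param estimate observed statistic.
#' @param sd standard deviation (`> 0`).
#' @param v_minus,v_plus truncation interval (may be infinite).
#' @param null_mean reference mean (default 0).
#' @param two_sided return the conservative two-sided value (default) or
#'   the upper-tail one-sided value.
#' @return p-value in `[0, 1]`.
#' @export
truncated_gaussian_pvalue <- function(estimate, sd, v_minus, v_plus,
                                      null_mean = 0, two_sided = TRUE) {
  stopifnot(sd > 0, v_minus < v_plus)
  if (estimate < v_minus || estimate > v_plus)
    stop("estimate outside truncation interval")
  p_up <- tnorm_surv_ratio((estimate - null_mean) / sd,
                           (v_minus - null_mean) / sd,
                           (v_plus - null_mean) / sd)
  if (!two_sided) return(p_up)
  min(1, 2 * min(p_up, 1 - p_up))
}

# P(Z > t | a < Z < b) for standard normal Z, via stable log-tail arithmetic
tnorm_surv_ratio <- function(t, a, b) {
  if (t <= a) return(1)
  if (t >= b) return(0)
  ls <- function(x) pnorm(x, lower.tail = FALSE, log.p = TRUE)
  # work in whichever tail is better conditioned
  if (t >= 0 || b <= 0) {
    num <- logspace_sub(ls(t), ls(b))
    den <- logspace_sub(ls(a), ls(b))
  } else {
    lc <- function(x) pnorm(x, log.p = TRUE)
    num <- logspace_sub(lc(b), lc(t))
    den <- logspace_sub(lc(b), lc(a))
  }
  if (!is.finite(den)) return(NaN)
  min(1, max(0, exp(num - den)))
}

# log(exp(lx) - exp(ly)) for lx >= ly
logspace_sub <- function(lx, ly) {
  if (ly == -Inf) return(lx)
  lx + log1p(-exp(ly - lx))
}

#' Selective inference for a LASSO-selected logistic model
#'
#' Conditions on the observed active set and sign vector of a LASSO
#' (`alpha = 1`) logistic fit at fixed `lambda`. The target is the one-step
#' debiased estimator on the active set,
#' `beta_bar = beta_hat - H^{-1} g = beta_hat + lambda * H^{-1} (0, s)`,
#' with `H` the average-information matrix at the LASSO solution and
#' asymptotic covariance `H^{-1}/n`. The selection event
#' `sign(beta_hat_E) = s` is affine in `beta_bar`, so the polyhedral lemma
#' yields, for each active coefficient, a truncation interval `[V-, V+]`
#' and a truncated-Gaussian p-value; the conservative two-sided rule
#' doubles the smaller tail and caps at 1. Per-allele adjusted odds ratios
#' come from the debiased estimate on the original predictor scale (the
#' shrunken LASSO coefficient is available via `or_source = "lasso"`).
#'
#' @param X design matrix (original scale, no missing values).
#' @param y binary 0/1 outcome.
#' @param lambda the fixed penalty at which the model was selected.
#' @param fit optional converged `enet_fit` at `alpha = 1` and `lambda`
#'   (refit internally when omitted).
#' @param or_source `"debiased"` (default) or `"lasso"`.
#' @return data.frame of class `selective_inference`, one row per selected
#'   predictor: `name`, `estimate` (per-unit log-odds), `stderr`, `or_adj`,
#'   `p_selective`, `v_minus`, `v_plus`.
#' @export
selective_inference <- function(X, y, lambda, fit = NULL,
                                or_source = c("debiased", "lasso")) {
  or_source <- match.arg(or_source)
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(fit))
    fit <- fit_enet_logistic(X, y, alpha = 1, lambda = lambda)
  stopifnot(inherits(fit, "enet_fit"), fit$alpha == 1)
  E <- fit$active_set
  if (length(E) == 0) {
    warning("empty active set: nothing selected at this lambda")
    return(empty_selective_result())
  }
  s <- fit$signs
  # standardized active design with intercept
  Xs <- sweep(sweep(X[, E, drop = FALSE], 2, fit$center[E], "-"),
              2, fit$scale[E], "/")
  M <- cbind(1, Xs)
  b_hat <- c(fit$intercept + sum(fit$coefs * fit$center), fit$coefs_std[E])
  p_hat <- fit$fitted
  w <- p_hat * (1 - p_hat)
  H <- crossprod(M * w, M) / n
  cond <- tryCatch(kappa(H, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cond) || cond > 1e10)
    stop("ill-conditioned active-set information matrix; collinear predictors: ",
         paste(colnames(X)[E], collapse = ", "))
  Hinv <- solve(H)
  pf_E <- fit$penalty_factors[E]
  offset <- lambda * drop(Hinv %*% c(0, s * pf_E))   # H^{-1} (0, s)
  beta_bar <- b_hat + offset
  Sigma <- Hinv / n
  # selection event: s_j * (beta_bar_j - offset_j) > 0 for active coords
  k <- length(E)
  A <- matrix(0, k, k + 1)
  A[cbind(seq_len(k), seq_len(k) + 1)] <- -s
  b_vec <- -s * offset[-1]
  out <- lapply(seq_len(k), function(jj) {
    j <- jj + 1
    sd_j <- sqrt(Sigma[j, j])
    eta_cov <- Sigma[, j]
    c_vec <- eta_cov / Sigma[j, j]
    t_obs <- beta_bar[j]
    rho <- drop(A %*% c_vec)
    num <- b_vec - drop(A %*% beta_bar) + rho * t_obs
    v_minus <- suppressWarnings(max((num / rho)[rho < -1e-12], -Inf))
    v_plus <- suppressWarnings(min((num / rho)[rho > 1e-12], Inf))
    # numerical guard: observed value must sit inside its own interval
    v_minus <- min(v_minus, t_obs)
    v_plus <- max(v_plus, t_obs)
    p <- truncated_gaussian_pvalue(t_obs, sd_j, v_minus, v_plus)
    est_orig <- t_obs / fit$scale[E[jj]]
    if (or_source == "lasso") est_orig <- fit$coefs[E[jj]]
    data.frame(name = names(fit$coefs)[E[jj]],
               estimate = est_orig,
               stderr = sd_j / fit$scale[E[jj]],
               or_adj = exp(est_orig),
               p_selective = p,
               v_minus = v_minus / fit$scale[E[jj]],
               v_plus = v_plus / fit$scale[E[jj]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("selective_inference", "data.frame")
  res
}

empty_selective_result <- function() {
  res <- data.frame(name = character(0), estimate = numeric(0),
                    stderr = numeric(0), or_adj = numeric(0),
                    p_selective = numeric(0), v_minus = numeric(0),
                    v_plus = numeric(0), stringsAsFactors = FALSE)
  class(res) <- c("selective_inference", "data.frame")
  res
}

#' Adjusted-odds-ratio report for the CV-selected LASSO model
#'
#' Refits the LASSO at the cross-validation optimum, runs
#' [selective_inference()], and formats one row per selected predictor —
#' clinical covariates first, then SNVs labelled
#' `"GENE: Chr.C pos.P REF>ALT"` — with the per-allele adjusted odds ratio
#' and selective p-value. Mirrors the shape of a multivariate
#' association-results table; no confidence intervals are emitted because
#' there is no established interval construction for this estimator.
#'
#' @param design a `design_matrix` from [build_design()] /
#'   [filter_pipeline()].
#' @param cv a `cv_result` from [grid_search()] (its `best_lam` is used;
#'   inference assumes `best_alpha = 1`, and other alphas fall back to a
#'   LASSO refit at `best_lam` with a warning).
#' @param snv_meta SNV metadata (from the `genotype_matrix`) used for row
#'   labels.
#' @return data.frame of class `table2_report`.
#' @export
table2_report <- function(design, cv, snv_meta = NULL) {
  X <- design$X; y <- design$y
  if (cv$best_alpha != 1)
    warning("CV optimum has alpha = ", cv$best_alpha,
            "; selective inference applies to the LASSO refit at best_lam")
  fit <- fit_enet_logistic(X, y, alpha = 1, lambda = cv$best_lam)
  si <- selective_inference(X, y, cv$best_lam, fit = fit)
  if (nrow(si) == 0) return(si)
  clinical <- design$predictor_names[seq_len(design$n_clinical)]
  si$factor <- si$name
  if (!is.null(snv_meta)) {
    m <- match(si$name, snv_meta$id)
    snv <- !is.na(m)
    si$factor[snv] <- sprintf("%s: Chr.%s pos.%d %s>%s",
                              snv_meta$gene[m[snv]], snv_meta$chrom[m[snv]],
                              snv_meta$pos[m[snv]], snv_meta$ref[m[snv]],
                              snv_meta$alt[m[snv]])
  }
  ord <- order(!(si$name %in% clinical),
               match(si$name, design$predictor_names))
  out <- si[ord, c("factor", "name", "or_adj", "p_selective", "estimate",
                   "stderr")]
  rownames(out) <- NULL
  class(out) <- c("table2_report", "data.frame")
  out
}
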