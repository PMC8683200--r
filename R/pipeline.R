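#' Analysis run configuration
#'
#' Validated container of every tunable the full pipeline uses: input paths
#' (or a synthetic [cohort_spec()]), the filtering thresholds (variation 2%,
#' missingness 5%, AUDIT cutoff 8), the cross-validation grid (alphas
#' `{0, 0.5, 1}`, 100 lambdas, path floor ratio), the positive outcome
#' (`ex_smoker` models nonsmoking status), inference options, and the seed.
#'
#' @param genotype_path,phenotype_path input files (TSV dosage + sidecar,
#'   phenotype CSV); omit both to analyze `synthetic_spec`.
#' @param synthetic_spec a [cohort_spec()] used when no paths are given.
#' @param variation_threshold,missingness_threshold,audit_cutoff filtering
#'   thresholds.
#' @param alphas,n_lambda,min_ratio CV grid.
#' @param outcome_positive `"ex_smoker"` or `"smoker"`.
#' @param or_source `"debiased"` or `"lasso"` adjusted-OR source.
#' @param seed root seed; stages derive their own streams from it.
#' @param out_dir output directory (created if needed).
#' @return list of class `run_config`.
#' @export
run_config <- function(genotype_path = NULL, phenotype_path = NULL,
                       synthetic_spec = NULL,
                       variation_threshold = 0.02,
                       missingness_threshold = 0.05, audit_cutoff = 8,
                       alphas = c(0, 0.5, 1), n_lambda = 100,
                       min_ratio = 0.01,
                       outcome_positive = c("ex_smoker", "smoker"),
                       or_source = c("debiased", "lasso"),
                       seed = 1L, out_dir = tempfile("cessnet_run_")) {
  outcome_positive <- match.arg(outcome_positive)
  or_source <- match.arg(or_source)
  problems <- character(0)
  if (!(variation_threshold > 0 && variation_threshold < 1))
    problems <- c(problems, "variation_threshold must be in (0, 1)")
  if (!(missingness_threshold > 0 && missingness_threshold < 1))
    problems <- c(problems, "missingness_threshold must be in (0, 1)")
  if (length(alphas) == 0 || any(alphas < 0 | alphas > 1))
    problems <- c(problems, "alphas must be a non-empty subset of [0, 1]")
  if (n_lambda < 1) problems <- c(problems, "n_lambda must be >= 1")
  if (audit_cutoff < 0 || audit_cutoff > 40)
    problems <- c(problems, "audit_cutoff must be within the AUDIT range 0-40")
  has_paths <- !is.null(genotype_path) || !is.null(phenotype_path)
  if (has_paths && (is.null(genotype_path) || is.null(phenotype_path)))
    problems <- c(problems, "genotype_path and phenotype_path must be given together")
  if (!has_paths && is.null(synthetic_spec))
    problems <- c(problems, "either input paths or a synthetic_spec is required")
  if (length(problems))
    stop("invalid run configuration:\n  - ", paste(problems, collapse = "\n  - "))
  structure(list(genotype_path = genotype_path,
                 phenotype_path = phenotype_path,
                 synthetic_spec = synthetic_spec,
                 variation_threshold = variation_threshold,
                 missingness_threshold = missingness_threshold,
                 audit_cutoff = audit_cutoff, alphas = alphas,
                 n_lambda = n_lambda, min_ratio = min_ratio,
                 outcome_positive = outcome_positive, or_source = or_source,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Sequence: univariate characteristics table, SNV filtering cascade to a
#' regression-ready design, LOO-CV AUC grid search over (alpha, lambda),
#' LASSO refit at the optimum, selective inference, adjusted-OR report.
#' Writes `table1.tsv`, `filter_report.json`, `cv_grid.tsv`, `table2.tsv`
#' and `run_log.json` (all effective parameters, the seed, and the chosen
#' grid point including `log(lambda)`) into `config$out_dir`. Identical
#' config and inputs give identical outputs.
#'
#' @param config a [run_config()].
#' @return invisible list with `table1`, `filter_report`, `cv`, `table2`,
#'   and the output paths.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)     # no partial output bundles
    stop(e)
  }
  tryCatch({
    if (!is.null(config$genotype_path)) {
      G <- read_genotype_matrix(config$genotype_path)
      pheno <- read_phenotypes(config$phenotype_path)
    } else {
      cohort <- generate_cohort(config$synthetic_spec)
      G <- cohort$genotypes
      pheno <- cohort$phenotypes
    }
    t1 <- table1_report(pheno, audit_cutoff = config$audit_cutoff)
    p_t1 <- file.path(config$out_dir, "table1.tsv")
    write_report(t1, p_t1, "tsv"); written <- c(written, p_t1)

    fp <- filter_pipeline(G, pheno,
                          variation_threshold = config$variation_threshold,
                          missingness_threshold = config$missingness_threshold,
                          outcome_positive = config$outcome_positive,
                          audit_cutoff = config$audit_cutoff)
    p_fr <- file.path(config$out_dir, "filter_report.json")
    write_report(unclass(fp$report), p_fr, "json"); written <- c(written, p_fr)

    set.seed(config$seed)
    cv <- grid_search(fp$design$X, fp$design$y, alphas = config$alphas,
                      n_lambda = config$n_lambda,
                      min_ratio = config$min_ratio)
    p_cv <- file.path(config$out_dir, "cv_grid.tsv")
    write_report(cv$grid, p_cv, "tsv"); written <- c(written, p_cv)

    t2 <- table2_report(fp$design, cv, snv_meta = G$snv_meta)
    p_t2 <- file.path(config$out_dir, "table2.tsv")
    write_report(as.data.frame(t2), p_t2, "tsv"); written <- c(written, p_t2)

    log <- list(seed = config$seed,
                parameters = config[c("variation_threshold",
                                      "missingness_threshold", "audit_cutoff",
                                      "alphas", "n_lambda", "min_ratio",
                                      "outcome_positive", "or_source")],
                selected = list(alpha = cv$best_alpha, lambda = cv$best_lam,
                                log_lambda = log(cv$best_lam),
                                loo_auc = cv$best_auc),
                filter = fp$report[c("n_input_snvs", "n_low_variation",
                                     "n_high_missing", "n_duplicate_collapsed",
                                     "n_retained_snvs", "n_input_samples",
                                     "n_complete_case")])
    p_log <- file.path(config$out_dir, "run_log.json")
    write_report(log, p_log, "json"); written <- c(written, p_log)

    invisible(list(table1 = t1, filter_report = fp$report, design = fp$design,
                   cv = cv, table2 = t2, paths = written))
  }, error = on_fail)
}

#' Internal consistency self-check on a seeded fixture
#'
#' Runs the filter accounting identity and the KKT stationarity check on a
#' small synthetic cohort and reports pass/fail counts; a cheap smoke test
#' of the fitted machinery.
#'
#' @param seed fixture seed.
#' @return list with `passed`, `failed`, `checks`.
#' @export
self_check <- function(seed = 7L) {
  spec <- cohort_spec(n_samples = 80, n_snvs = 60, n_low_variation = 6,
                      n_high_missing = 10, n_duplicate = 4,
                      n_incomplete_pheno = 8, seed = seed)
  cohort <- generate_cohort(spec)
  fp <- filter_pipeline(cohort$genotypes, cohort$phenotypes)
  r <- fp$report
  checks <- c(
    filter_accounting = r$n_retained_snvs ==
      r$n_input_snvs - r$n_low_variation - r$n_high_missing -
      r$n_duplicate_collapsed,
    complete_case_bound = r$n_complete_case <= r$n_input_samples,
    design_no_missing = !anyNA(fp$design$X))
  lams <- lambda_path(fp$design$X, fp$design$y, alpha = 1, n_lambda = 10)
  fits <- fit_enet_path(fp$design$X, fp$design$y, 1, lams)
  kkt <- vapply(fits, function(f) kkt_check(f, fp$design$X, fp$design$y),
                numeric(1))
  checks <- c(checks,
              kkt_below_tol = max(kkt) < 1e-4,
              all_zero_at_lambda_max = length(fits[[1]]$active_set) == 0)
  list(passed = sum(checks), failed = sum(!checks), checks = checks)
}
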