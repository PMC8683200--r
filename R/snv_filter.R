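REGRESSION_COVARIATES <- c("hazardous_alcohol", "marijuana_30d",
                           "cocaine_30d", "gad7")

#' Complete-case participant filter
#'
#' Retains participants with every listed regression covariate non-missing.
#' `"hazardous_alcohol"` requires a non-missing AUDIT score (it is derived
#' from it).
#'
#' @param pheno a `phenotype_table`.
#' @param covariates covariate names; default the four regression covariates
#'   (hazardous alcohol, past-30-day marijuana, past-30-day cocaine, GAD-7
#'   anxiety score).
#' @return character vector of retained sample ids.
#' @export
complete_case <- function(pheno, covariates = REGRESSION_COVARIATES) {
  if (length(covariates) == 0) return(pheno$sample_id)
  cols <- vapply(covariates, function(cv) {
    switch(cv,
           hazardous_alcohol = "audit_score",
           {
             if (!cv %in% names(pheno)) stop("unknown covariate: ", cv)
             cv
           })
  }, character(1))
  ok <- rowSums(is.na(pheno[, cols, drop = FALSE])) == 0
  pheno$sample_id[ok]
}

# fraction of non-missing genotypes differing from the modal genotype,
# per SNV column
nonmodal_fraction <- function(dosage) {
  apply(dosage, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    counts <- tabulate(x + 1, nbins = 3)
    1 - max(counts) / length(x)
  })
}

minor_allele_frequency <- function(dosage) {
  apply(dosage, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    f <- sum(x) / (2 * length(x))
    min(f, 1 - f)
  })
}

#' Low-variation SNV filter
#'
#' Removes SNVs whose variation, measured as the fraction of non-missing
#' genotypes differing from the modal genotype (or the minor allele
#' frequency with `metric = "maf"`), is below `threshold`. SNVs with zero
#' non-missing calls are removed at this stage.
#'
#' @param G a [genotype_matrix()].
#' @param threshold variation threshold (default 0.02).
#' @param samples optional sample ids over which variation is computed
#'   (defaults to all).
#' @param metric `"nonmodal"` (default) or `"maf"`.
#' @return list with `retained` and `removed` SNV id vectors.
#' @export
variation_filter <- function(G, threshold = 0.02, samples = NULL,
                             metric = c("nonmodal", "maf")) {
  metric <- match.arg(metric)
  stopifnot(threshold > 0, threshold <= 0.5)
  d <- subset_dosage(G, samples)
  frac <- if (metric == "nonmodal") nonmodal_fraction(d)
          else minor_allele_frequency(d)
  removed <- colnames(d)[is.na(frac) | frac < threshold]
  list(retained = setdiff(colnames(d), removed), removed = removed)
}

#' High-missingness SNV filter
#'
#' Removes SNVs whose missing-call fraction is `>= threshold`.
#'
#' @inheritParams variation_filter
#' @param threshold missing-rate threshold (default 0.05).
#' @param snvs optional SNV ids to consider (defaults to all).
#' @return list with `retained` and `removed` SNV id vectors.
#' @export
missingness_filter <- function(G, threshold = 0.05, samples = NULL,
                               snvs = NULL) {
  d <- subset_dosage(G, samples, snvs)
  miss <- colMeans(is.na(d))
  removed <- colnames(d)[miss >= threshold]
  list(retained = setdiff(colnames(d), removed), removed = removed)
}

#' Collapse SNVs with identical genotype profiles
#'
#' Among each group of SNVs whose genotype vectors are identical over the
#' given samples (missing calls compare equal), exactly one — the
#' lexicographically first id — is retained.
#'
#' @inheritParams missingness_filter
#' @return list with `retained` and `removed` SNV id vectors.
#' @export
collapse_identical <- function(G, samples = NULL, snvs = NULL) {
  d <- subset_dosage(G, samples, snvs)
  ids <- colnames(d)
  key <- apply(d, 2, function(x) paste(ifelse(is.na(x), ".", x), collapse = ""))
  removed <- character(0)
  for (grp in split(ids, key)) {
    if (length(grp) > 1) removed <- c(removed, sort(grp)[-1])
  }
  removed <- sort(removed)
  list(retained = setdiff(ids, removed), removed = removed)
}

subset_dosage <- function(G, samples = NULL, snvs = NULL) {
  d <- G$dosage
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, rownames(d))
    if (length(missing_s))
      stop("samples absent from genotype matrix: ",
           paste(missing_s, collapse = ", "))
    d <- d[samples, , drop = FALSE]
  }
  if (!is.null(snvs)) d <- d[, snvs, drop = FALSE]
  d
}

#' Build the regression design matrix
#'
#' Assembles clinical covariates (hazardous alcohol 0/1, marijuana 0/1,
#' cocaine 0/1, GAD-7 score) followed by SNV dosages (additive 0/1/2
#' coding) for the retained samples. Residual missing dosages (below the
#' missingness threshold by construction) are imputed to the column modal
#' genotype by default, which preserves the `{0,1,2}` support; `"mean"`
#' imputation is available behind the flag.
#'
#' @param G a [genotype_matrix()].
#' @param pheno a `phenotype_table`.
#' @param retained_snvs SNV ids to include.
#' @param retained_samples sample ids to include (must be complete cases for
#'   the clinical covariates).
#' @param outcome_positive which outcome is coded `y = 1`; the default
#'   `"ex_smoker"` models nonsmoking status.
#' @param impute `"mode"` (default) or `"mean"`.
#' @param audit_cutoff AUDIT threshold for the hazardous-alcohol indicator.
#' @return list of class `design_matrix` with `X`, `y`, `sample_ids`,
#'   `predictor_names`, `n_clinical`.
#' @export
build_design <- function(G, pheno, retained_snvs, retained_samples,
                         outcome_positive = c("ex_smoker", "smoker"),
                         impute = c("mode", "mean"), audit_cutoff = 8) {
  outcome_positive <- match.arg(outcome_positive)
  impute <- match.arg(impute)
  d <- subset_dosage(G, retained_samples, retained_snvs)
  ph <- pheno[match(retained_samples, pheno$sample_id), ]
  if (anyNA(ph$sample_id))
    stop("retained samples absent from phenotype table")
  clin <- cbind(
    hazardous_alcohol = as.numeric(ph$audit_score >= audit_cutoff),
    marijuana_30d = as.numeric(ph$marijuana_30d),
    cocaine_30d = as.numeric(ph$cocaine_30d),
    anxiety_gad7 = as.numeric(ph$gad7))
  if (anyNA(clin))
    stop("clinical covariates contain missing values; apply complete_case first")
  for (j in seq_len(ncol(d))) {
    miss <- is.na(d[, j])
    if (any(miss)) {
      obs <- d[!miss, j]
      fill <- if (length(obs) == 0) 0
              else if (impute == "mode") modal_value(obs)
              else mean(obs)
      d[miss, j] <- fill
    }
  }
  X <- cbind(clin, d)
  rownames(X) <- retained_samples
  y <- as.numeric(ph$outcome == outcome_positive)
  structure(list(X = X, y = y, sample_ids = retained_samples,
                 predictor_names = colnames(X), n_clinical = ncol(clin),
                 outcome_positive = outcome_positive),
            class = "design_matrix")
}

modal_value <- function(x) {
  counts <- tabulate(x + 1, nbins = 3)
  which.max(counts) - 1   # ties broken toward the smaller dosage
}

#' Run the full SNV filtering cascade
#'
#' Stage order: complete-case participant subsetting, then (over the
#' complete-case samples) the low-variation filter, the high-missingness
#' filter, duplicate-profile collapse, and design-matrix assembly. The
#' returned report accounts for every input SNV exactly once.
#'
#' @inheritParams build_design
#' @param variation_threshold fraction below which an SNV is considered
#'   invariant (default 0.02).
#' @param missingness_threshold missing-rate at or above which an SNV is
#'   dropped (default 0.05).
#' @param covariates complete-case covariates (default the four regression
#'   covariates).
#' @param variation_metric `"nonmodal"` or `"maf"`.
#' @return list with `design` (a `design_matrix`) and `report` (a
#'   `filter_report`).
#' @export
filter_pipeline <- function(G, pheno, variation_threshold = 0.02,
                            missingness_threshold = 0.05,
                            covariates = REGRESSION_COVARIATES,
                            outcome_positive = c("ex_smoker", "smoker"),
                            variation_metric = c("nonmodal", "maf"),
                            impute = c("mode", "mean"), audit_cutoff = 8) {
  outcome_positive <- match.arg(outcome_positive)
  variation_metric <- match.arg(variation_metric)
  impute <- match.arg(impute)
  cc <- complete_case(pheno, covariates)
  cc <- intersect(pheno$sample_id, cc)  # preserve phenotype order
  v <- variation_filter(G, variation_threshold, samples = cc,
                        metric = variation_metric)
  m <- missingness_filter(G, missingness_threshold, samples = cc,
                          snvs = v$retained)
  dup <- collapse_identical(G, samples = cc, snvs = m$retained)
  design <- build_design(G, pheno, dup$retained, cc,
                         outcome_positive = outcome_positive, impute = impute,
                         audit_cutoff = audit_cutoff)
  report <- structure(list(
    n_input_snvs = ncol(G$dosage),
    n_low_variation = length(v$removed),
    n_high_missing = length(m$removed),
    n_duplicate_collapsed = length(dup$removed),
    n_retained_snvs = length(dup$retained),
    n_input_samples = nrow(G$dosage),
    n_complete_case = length(cc),
    removed_ids = list(low_variation = v$removed, high_missing = m$removed,
                       duplicate = dup$removed),
    retained_snvs = dup$retained,
    complete_case_samples = cc), class = "filter_report")
  list(design = design, report = report)
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat("SNV filter cascade:\n",
      "  input SNVs:          ", x$n_input_snvs, "\n",
      "  - low variation:     ", x$n_low_variation, "\n",
      "  - high missingness:  ", x$n_high_missing, "\n",
      "  - duplicate profile: ", x$n_duplicate_collapsed, "\n",
      "  retained SNVs:       ", x$n_retained_snvs, "\n",
      "  samples: ", x$n_input_samples, " -> ", x$n_complete_case,
      " complete cases\n", sep = "")
  invisible(x)
}
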