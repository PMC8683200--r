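# cessnet

Penalized candidate-gene association analysis of long-term smoking
cessation in case-control cohorts.

## What it is for

Cohort studies of persons with HIV who smoke ask which behavioral
characteristics and which single-nucleotide variants (SNVs) in candidate
genes (*SLC25A21*, *CHRNA3/4/5*, *CADM2*, *DNMT3B*, ...) distinguish
successful long-term quitters from current smokers. The sample sizes are
small (n in the low hundreds), the SNV panels are wide (hundreds of
variants) and strongly autocorrelated, so the analysis needs penalized
regression and selection-aware inference rather than one-variant-at-a-time
testing. `cessnet` packages that analysis end to end:

1. **Univariate behavioral table** — per-characteristic 2x2 odds ratios
   (cross-product estimator, Woolf 95% CI, no continuity correction),
   chi-square / Fisher exact tests, and pooled-t / Mann-Whitney comparisons
   with per-variable missing-data denominators.
2. **SNV filtering cascade** — complete-case subsetting, a 2% variation
   filter, a 5% missingness filter, duplicate-profile collapse, and
   additive 0/1/2 design assembly with modal imputation.
3. **Elastic-net logistic regression** — coordinate descent with
   soft-thresholding on an IRLS quadratic approximation (compiled, with
   strong-rule screening and per-lambda KKT verification), minimizing
   `(1/n) Σ [log(1+e^η) − y η] + λ Σ pf_j (α|β_j| + (1−α)/2 β_j²)`.
4. **Model selection** — leave-one-out cross-validation over
   α ∈ {0, 0.5, 1} × 100 λ values, scored by the pooled rank-based AUC,
   ties broken toward the sparser model.
5. **Post-selection inference** — polyhedral-lemma truncated-Gaussian
   p-values for the LASSO-selected coefficients (one-step debiased
   estimator, conservative two-sided rule) and per-allele adjusted odds
   ratios.
6. **Synthetic cohorts** — a seeded generator (Hardy-Weinberg genotypes,
   Gaussian-copula LD blocks, planted effects, structured missingness) and
   a deterministic study-mirror fixture, so everything is testable without
   access to individual-level data.

See `vignettes/cessnet-methods.Rmd` for the models, assumptions, numerical
choices and limitations.

## Worked example

```r
library(cessnet)

cohort <- paper_mirror_fixture()      # deterministic 194 x 759 cohort
fp <- filter_pipeline(cohort$genotypes, cohort$phenotypes)
fp$report
#> SNV filter cascade:
#>   input SNVs:          759
#>   - low variation:     124
#>   - high missingness:  458
#>   - duplicate profile: 21
#>   retained SNVs:       156
#>   samples: 194 -> 157 complete cases

t1 <- table1_report(cohort$phenotypes)
t1[t1$variable %in% c("marijuana_30d", "cocaine_30d", "hazardous_alcohol"),
   c("variable", "or_point", "ci_low", "ci_high", "p_value")]
#>            variable or_point ci_low ci_high  p_value
#> 6 hazardous_alcohol     5.42   1.23   23.86 0.013496
#> 7     marijuana_30d     3.74   1.69    8.26 0.000691
#> 8       cocaine_30d    17.16   2.29  128.84 0.000254

set.seed(1)
cv <- grid_search(fp$design$X, fp$design$y)
cv
#> cv_result: LOO (157 folds, pooled AUC) over 300 grid points
#>   best: alpha=0.5, lambda=0.1218 (log -2.105), AUC=0.754

t2 <- table2_report(fp$design, cv, snv_meta = cohort$genotypes$snv_meta)
head(t2[, c("factor", "or_adj", "p_selective")])
#>                              factor or_adj p_selective
#> 1 SLC25A21: Chr.14 pos.37148248 T>C   4.39     1.8e-05
```

Reading the output: the filtering cascade reduces 759 SNVs to 156 and 194
participants to 157 complete cases; marijuana and cocaine use are strongly
associated with *current* smoking (ORs 3.7 and 17.2); cross-validation
picks a penalized model with pooled leave-one-out AUC 0.75; and the
selective-inference report finds the planted *SLC25A21* variant with an
adjusted per-allele odds ratio of 4.4 for being an ex-smoker — the fixture
plants that effect deliberately so the end-to-end surface is non-trivial.
(When the CV optimum is not α = 1, as here, inference applies to the LASSO
refit at the selected λ and says so in a warning.)

The same pipeline runs on your own files via
`run_full_analysis(run_config(genotype_path = ..., phenotype_path = ...))`
(dosage TSV + metadata sidecar or VCF, phenotype CSV; see
`?read_genotype_matrix`), or from a shell through
`scripts/cessnet_cli.R {simulate|table1|analyze|check}`.

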