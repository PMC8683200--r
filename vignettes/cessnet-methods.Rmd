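---
title: "Penalized candidate-gene analysis of long-term smoking cessation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized candidate-gene analysis of long-term smoking cessation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cessnet)
```

## The scientific setting

`cessnet` implements an analysis pipeline for a case-control question in
genetic epidemiology: among persons with HIV who have ever smoked, which
behavioral characteristics and which single-nucleotide variants (SNVs) in a
panel of candidate genes distinguish successful long-term quitters
(ex-smokers) from current or recent smokers?

The data shape it expects is a cohort of a few hundred participants with

* a binary outcome (`ex_smoker` vs `smoker`),
* behavioral covariates — hazardous alcohol use (AUDIT score at or above 8),
  past-30-day marijuana use, past-30-day cocaine use, anxiety (GAD-7, 0-21),
  depression (CESD-20, 0-60), plus demographics, and
* several hundred SNV genotypes in candidate genes (e.g. *SLC25A21*,
  *CHRNA3*, *CADM2*), coded additively as 0/1/2 copies of the alternate
  allele, with realistic missingness.

Because individual-level cohorts of this kind are rarely deposited, the
package ships a synthetic-cohort generator (`generate_cohort()`) and a
deterministic study-mirror fixture (`paper_mirror_fixture()`) so the whole
pipeline can be exercised, tested and benchmarked without any external data.

## Pipeline stages

### 1. Univariate behavioral associations (`table1_report()`)

Each categorical characteristic is summarized as a 2x2 table against the
outcome, oriented so that an odds ratio above 1 means the exposure is
associated with *current smoking*. The OR is the cross-product
$(ad)/(bc)$ with the Woolf confidence interval
$\exp(\log \mathrm{OR} \pm z \sqrt{1/a + 1/b + 1/c + 1/d})$.
No continuity correction is applied by default (it is available behind
`haldane = TRUE`): a published cocaine-use OR of 17.2 is only reproducible
from its cell counts by the uncorrected estimator. Zero cells flag the OR as
infinite or undefined rather than being silently corrected.

Test choice follows standard practice, since sources of this design say
only "chi-square or Fisher exact, where appropriate": Fisher's exact test
when any expected cell count is below 5, otherwise the Pearson chi-square
without the Yates correction; for continuous covariates, the pooled-variance
t-test when both groups have |skewness| < 1, otherwise the Mann-Whitney test
with mid-ranks and the normal approximation. Per-variable denominators
reflect per-variable missingness; participants are only dropped from the
tables their missing value touches.

### 2. SNV filtering cascade (`filter_pipeline()`)

The cascade reduces a raw panel to a regression-ready design in a fixed
order:

1. **Complete cases** — participants missing any regression covariate
   (hazardous alcohol, marijuana, cocaine, GAD-7) are removed. All later
   stages are computed over the remaining participants, because duplicate
   detection is only meaningful "among these subjects".
2. **Variation filter** (threshold 0.02) — an SNV is removed when the
   fraction of non-missing genotypes differing from the modal genotype is
   below 2%. "Variation" is ambiguous in the field; we read it as
   variability of the coded value, and offer minor-allele frequency as an
   alternative metric (`variation_metric = "maf"`).
3. **Missingness filter** (threshold 0.05) — removed when the missing-call
   rate is at least 5%.
4. **Duplicate-profile collapse** — among SNVs with identical genotype
   vectors over the complete-case samples, the lexicographically first id
   is kept.
5. **Design assembly** — clinical covariates (0/1 indicators, GAD-7 as an
   integer score) followed by SNV dosages. Residual missing dosages (below
   5% per column by construction) are imputed to the column modal genotype,
   which keeps the additive support {0,1,2}; mean imputation is available
   behind a flag. The outcome codes `ex_smoker` as 1 by default, so
   coefficients are per-allele log-odds of successful quitting.

The `filter_report` satisfies an exact accounting identity (retained =
input − low-variation − high-missing − duplicates), enforced by a property
test over random cohorts.

### 3. Elastic-net logistic regression (`fit_enet_logistic()`)

The penalized fit minimizes

$$\frac{1}{n}\sum_i \left[\log(1 + e^{\eta_i}) - y_i \eta_i\right]
  + \lambda \sum_j pf_j \left(\alpha |\beta_j| +
  \tfrac{1-\alpha}{2}\beta_j^2\right),
  \qquad \eta = \beta_0 + X\beta,$$

by cyclic coordinate descent with soft-thresholding inside an iteratively
reweighted least-squares (IRLS) quadratic approximation — the standard
algorithm for this problem class — implemented in compiled code with
sequential strong-rule screening and a full per-lambda Karush-Kuhn-Tucker
(KKT) verification, so screening never changes the solution. Columns are
standardized internally to unit 1/n-variance ($\lambda$ lives on that
scale); coefficients are reported back on the original per-allele scale.
The intercept is never penalized; per-column `penalty_factors` allow
clinical covariates to be exempted, though the default penalizes all
predictors equally (the selected models in this design report clinical
covariates alongside SNVs, consistent with uniform penalization).

Numerical choices: convergence tolerance `1e-7` on the maximum
standardized-coefficient change (inner coordinate sweeps at a tenth of
that), IRLS weights floored at `1e-5`, linear predictors clipped at ±30,
and `lambda_path()` anchored at
$\lambda_{\max} = \max_j |\tilde x_j^\top (y - \bar y)| / (n\alpha)$
— inflated by one part in $10^9$ so the all-zero solution is reproduced
exactly at the path head — descending log-uniformly over 100 values to
`min_ratio = 0.01` of the maximum (the usual floor when p > n). Pure ridge
($\alpha = 0$) has no finite $\lambda_{\max}$, so its path is anchored at
the $\alpha = 0.001$ value, keeping the three paths comparable across the
mixing grid. Convergence of every reported fit is certified by
`kkt_check()`, the maximum stationarity violation over coordinates.

### 4. Model selection by leave-one-out cross-validated AUC (`grid_search()`)

For each $\alpha \in \{0, 0.5, 1\}$ and 100 values of $\lambda$, each of
the $n$ folds refits on $n-1$ samples (standardization recomputed inside
the fold, so nothing leaks from the held-out sample) and predicts the
held-out probability; the $n$ pooled predictions give one rank-based
(Mann-Whitney) AUC per grid point. Pooling is forced by the design: a
single-sample fold has no per-fold AUC. Ties on the grid break toward
larger $\lambda$, then larger $\alpha$ — the sparser, more-LASSO model —
which also makes selection deterministic.

Two properties of pooled LOO worth knowing:

* At the intercept-only end of the path the fold prediction is the training
  base rate, which moves *against* the held-out label; the pooled AUC of
  the null model is therefore 0, not 0.5. This is a well-known LOO
  artifact, not a bug; the AUC of genuinely constant scores is exactly 0.5
  by the mid-rank convention.
* CV scoring runs the solver with prediction-grade caps (tolerance `1e-3`,
  at most 8 IRLS steps and 15 coordinate sweeps per $\lambda$, and a fold's
  path is frozen once its training data are perfectly separated with mean
  log-loss below 0.1, after which only the sharpness of the probabilities
  changes). We verified on both a signal-rich fixture and permuted-null
  data that the selected $(\alpha, \lambda)$ and the AUC surface agree with
  full-precision runs to about three decimals; all *reported* fits are then
  recomputed at tolerance `1e-7` with a KKT certificate.

### 5. Post-selection inference (`selective_inference()`, `table2_report()`)

Refitting the LASSO at the CV-chosen $\lambda$ yields an active set $E$ and
sign vector $s$. Naive p-values for the selected coefficients would ignore
that the same data chose $E$; the package instead computes selective
p-values by the polyhedral (truncated-Gaussian) framework, with a one-step
Gaussian approximation for the logistic case:

* the target is the one-step debiased estimator on the active set,
  $\bar\beta = \hat\beta + \lambda H^{-1}(0, s)$ with
  $H = \tfrac1n M^\top W M$ the average information at the LASSO solution
  and covariance $\Sigma = H^{-1}/n$;
* the selection event $\{\mathrm{sign}(\hat\beta_E) = s\}$ is affine in
  $\bar\beta$, so for each coefficient the event induces a truncation
  interval $[V^-, V^+]$ for its estimate given the orthogonal remainder;
* the p-value is the truncated-Gaussian tail ratio
  $\left[\bar\Phi(t/\sigma) - \bar\Phi(V^+/\sigma)\right] /
  \left[\bar\Phi(V^-/\sigma) - \bar\Phi(V^+/\sigma)\right]$, computed via
  log-survival differences so extreme tails stay accurate, two-sided by
  the conservative rule $\min(1,\, 2\min(p^+, 1-p^+))$.

$\lambda$ is treated as fixed when constructing the selection event — the
CV step is not conditioned on — matching common practice. Adjusted odds
ratios are $\exp$ of the debiased per-allele estimate on the original
scale (`or_source = "lasso"` exposes the shrunken coefficient instead). No
confidence intervals are emitted: there is no established interval
construction for this estimator, and reporting none is the honest choice.

Two consequences users should expect:

* **The factor of 2 at vanishing penalty.** With a single predictor and
  $\lambda \to 0$, the truncation boundary tends to 0, the conditioning
  retains half the reference mass, and the two-sided selective p-value
  tends to *twice* the classical Wald p-value. Selection adjustment is not
  free even when the penalty is negligible.
* **Calibration.** Under a seeded global null (independent SNVs, outcome
  independent of genotype) the selective p-values of selected variables are
  uniform — the acceptance suite checks a Kolmogorov-Smirnov test at the 1%
  level over 500 replicates and that the fraction below 0.05 stays within
  Monte-Carlo error of 0.05. This is the testable form of the claim that
  the procedure controls the error rate of selected discoveries.

## The synthetic cohort generator

`generate_cohort()` draws genotypes per SNV from Hardy-Weinberg equilibrium
with minor-allele frequency uniform on `maf_range`, with
linkage-disequilibrium structure imposed by a Gaussian copula: haplotypes in
blocks of `ld_block_size` adjacent SNVs share a latent factor with loading
$\sqrt{\rho}$ (`ld_rho`, default 0.7 over blocks of 5 — candidate-gene
panels are strongly autocorrelated, and the default encodes that without
pretending to a measured LD map). Behavioral covariates are drawn with
positive co-use coupling through a shared latent variable (marijuana,
cocaine and hazardous drinking co-occur in real cohorts); the outcome
follows a logistic model combining behavioral effects (defaults on the
scale of the reported univariate associations: alcohol −1.0, marijuana
−1.15, cocaine −2.4 per-use log-odds of being an ex-smoker, GAD-7 −0.08 per
point) and any planted per-allele `causal_effects`, anchored at a baseline
ex-smoker fraction of 52/194.

Planted pathologies exercise the filtering cascade: near-monomorphic
columns, columns with at least 5% missing calls, exact duplicate columns,
and participants with a blanked covariate.

`paper_mirror_fixture()` is different in kind: its counts are
*specification, not simulation*. Group sizes (142 smokers / 52 ex-smokers),
the behavioral 2x2 margins, the 37 incomplete participants, and a 759-SNV
panel of which exactly 124 fail the variation filter, 458 the missingness
filter and 21 the duplicate collapse (leaving 156) are assigned
deterministically; only continuous scores and the genotype fillers are
seeded draws. One *SLC25A21* column carries an ex-smoker-enriched allele so
end-to-end reports are non-trivial.

What the generator does **not** emulate: population stratification and
ancestry-correlated allele frequencies, Hardy-Weinberg violations,
genotyping batch effects, informative (non-random) missingness, and any
dependence between behavioral covariates and genotype. Passing tests on
synthetic cohorts therefore validate the *machinery* — accounting,
estimators, calibration — not robustness to those real-data complications.

## Problem sizes used in the test and acceptance suites

The suites run at the cohort's own scale where that is cheap (the 194 x 759
fixture, the 157 x 160 design, the full 3 x 100 grid) and at reduced but
adequate scale for Monte-Carlo checks: 50 label-permutation replicates for
the leakage guard, 500 global-null replicates at p = 30 for p-value
calibration, 100 replicates for planted-effect recovery at n = 157,
p = 156, and n = 20 000 for the large-sample consistency check of the
generator. These sizes give Monte-Carlo standard errors comfortably inside
the asserted margins.

## Known limitations

* The one-step Gaussian approximation behind the selective p-values is
  asymptotic; at n in the low hundreds with rare alleles its calibration
  is good (we test it) but not exact.
* Conditioning ignores the cross-validation step; p-values are valid for
  the selection event at fixed $\lambda$.
* The univariate module reproduces published two-decimal statistics up to
  one unit in the last printed digit; published tables themselves appear to
  round inconsistently in places (a Woolf upper bound printed as 125 where
  the formula gives ≈129), and the package does not attempt to reverse-
  engineer such entries.
* Multi-allelic variants are rejected, not split: the additive 0/1/2 coding
  is strictly biallelic.
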