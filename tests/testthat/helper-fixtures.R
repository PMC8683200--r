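# shared in-code fixtures; the study-mirror cohort is cached because several
# files exercise it
.fixture_cache <- new.env(parent = emptyenv())

mirror_cohort <- function() {
  if (is.null(.fixture_cache$mirror))
    .fixture_cache$mirror <- paper_mirror_fixture()
  .fixture_cache$mirror
}

mirror_design <- function() {
  if (is.null(.fixture_cache$mirror_fp)) {
    cohort <- mirror_cohort()
    .fixture_cache$mirror_fp <- filter_pipeline(cohort$genotypes,
                                                cohort$phenotypes)
  }
  .fixture_cache$mirror_fp
}

tiny_genotypes <- function() {
  dos <- matrix(c(0, 1, 2,
                  1, NA, 0), nrow = 3,
                dimnames = list(c("S1", "S2", "S3"), NULL))
  meta <- data.frame(id = c("rs_a", "rs_b"), chrom = c("14", "3"),
                     pos = c(37148248L, 86118206L), ref = c("T", "T"),
                     alt = c("C", "A"), gene = c("SLC25A21", "CADM2"),
                     stringsAsFactors = FALSE)
  genotype_matrix(dos, meta)
}

tiny_phenotypes <- function(n = 5) {
  data.frame(
    sample_id = sprintf("S%d", seq_len(n)),
    outcome = rep(c("smoker", "ex_smoker"), length.out = n),
    age = 50 + seq_len(n),
    gender = rep(c("male", "female"), length.out = n),
    race = rep(c("black", "white"), length.out = n),
    latino = rep(c(TRUE, FALSE), length.out = n),
    education = rep(c("less_than_hs", "hs_graduate"), length.out = n),
    audit_score = rep(c(8L, 3L), length.out = n),
    marijuana_30d = rep(c(TRUE, FALSE), length.out = n),
    cocaine_30d = rep(FALSE, n),
    cesd = rep(20L, n),
    gad7 = rep(c(5L, 9L), length.out = n),
    stringsAsFactors = FALSE)
}

# simple seeded logistic design for solver tests
sim_logistic <- function(n, p, beta, intercept = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- rbinom(n, 1, plogis(intercept + drop(X %*% beta)))
  list(X = X, y = y)
}

random_contingency <- function(max_cell = 40) {
  list(a = sample.int(max_cell, 1), b = sample.int(max_cell, 1),
       c = sample.int(max_cell, 1), d = sample.int(max_cell, 1))
}
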