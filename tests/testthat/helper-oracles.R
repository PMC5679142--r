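# Shared fixtures and independent oracles for the test suite.

# Cohorts and fitted objects reused across test files (built once per run).
.fixture_env <- new.env(parent = emptyenv())

cached_cohort <- function(n, seed) {
  key <- sprintf("cohort_n%d_s%d", n, seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_cohort(n, seed = seed)
  .fixture_env[[key]]
}

# 50k cohort classified under the percentile-based preset and scored.
cached_analysis <- function() {
  if (is.null(.fixture_env$analysis)) {
    co <- cached_cohort(50000, 1)
    cl <- suppressMessages(classify_mets(co, mets_criteria("table_footnote")))
    fit <- cmets(cl)
    cl$cmets <- fitted(fit)
    .fixture_env$analysis <- list(cohort = cl, fit = fit,
                                  latent = attr(co, "latent_severity"))
  }
  .fixture_env$analysis
}

# Brute-force Mann-Whitney AUC: explicit pair counting, ties as 1/2.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive scan oracle for the optimal cutoff: evaluates sens + spec at
# every listed threshold (in exact integer arithmetic, so true ties stay
# ties) and returns the smallest argmax.
cutoff_brute <- function(scores, labels) {
  thr <- c(sort(unique(scores)), Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  j <- vapply(thr, function(t) {
    sum(scores[labels == 1] >= t) * n_neg +
      sum(scores[labels == 0] < t) * n_pos
  }, numeric(1))
  thr[which(j == max(j))[1]]
}

# A constant external BP reference covering one age-year for both sexes.
write_flat_bp_reference <- function(path, age_years, sbp = 110, dbp = 75) {
  grid <- expand.grid(sex = c("male", "female"), age_year = age_years,
                      height_percentile_band = 1:3)
  grid$sbp_p90 <- sbp
  grid$dbp_p90 <- dbp
  utils::write.csv(grid, path, row.names = FALSE)
  path
}
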