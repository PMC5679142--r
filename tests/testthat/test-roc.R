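test_that("the ROC curve has the documented endpoints and monotone arms", {
  r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  i <- match(3, r$thresholds)
  expect_equal(r$sensitivity[i], 1)
  expect_equal(r$specificity[i], 1)
  # endpoints: lowest threshold gives (1, 0), the sentinel gives (0, 1)
  expect_equal(r$sensitivity[1], 1)
  expect_equal(r$specificity[1], 0)
  expect_equal(r$sensitivity[length(r$thresholds)], 0)
  expect_equal(r$specificity[length(r$thresholds)], 1)
  expect_true(all(diff(r$sensitivity) <= 0))
  expect_true(all(diff(r$specificity) >= 0))
  expect_error(roc_curve(c(1, 2), c(1, 1)), "positive and.*negative")
  expect_error(roc_curve(c(1, Inf), c(0, 1)), "finite")
})

test_that("tied scores collapse the curve to the degenerate operating points", {
  r <- roc_curve(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(length(r$thresholds), 2)
  expect_equal(r$sensitivity, c(1, 0))
  expect_equal(r$specificity, c(0, 1))
  expect_equal(auc(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(optimal_cutoff(r), "degenerate")
})

test_that("AUC equals brute-force pair counting on every 3v3 arrangement", {
  combos <- combn(6, 3)
  for (j in seq_len(ncol(combos))) {
    labels <- rep(0, 6)
    labels[combos[, j]] <- 1
    scores <- 1:6
    expect_identical(auc(scores, labels), auc_brute(scores, labels))
    expect_equal(auc(scores, labels, method = "trapezoid"),
                 auc_brute(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC and optimal cutoff match their oracles on random tied instances", {
  set.seed(77)
  for (rep in 1:300) {
    n <- sample(4:20, 1)
    scores <- sample(1:6, n, replace = TRUE)  # small grid forces ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    a_mw <- auc(scores, labels)
    expect_equal(a_mw, auc_brute(scores, labels), tolerance = 1e-14)
    expect_equal(auc(scores, labels, method = "trapezoid"), a_mw,
                 tolerance = 1e-12)
    r <- roc_curve(scores, labels)
    if (length(r$thresholds) > 2)
      expect_identical(optimal_cutoff(r), cutoff_brute(scores, labels))
  }
})

test_that("cutoff ties resolve to the minimum threshold", {
  scores <- c(1, 2, 3, 4)
  labels <- c(1, 0, 1, 0)
  # sens + spec peaks at 1 for thresholds 1 and +Inf; the smaller wins
  expect_equal(optimal_cutoff(roc_curve(scores, labels)), 1)
})

test_that("AUC is invariant under increasing transforms and flips with labels", {
  set.seed(123)
  scores <- rnorm(500)
  labels <- rbinom(500, 1, plogis(scores))
  f <- function(x) exp(x / 2)
  expect_equal(auc(f(scores), labels), auc(scores, labels))
  cut <- optimal_cutoff(roc_curve(scores, labels))
  expect_equal(optimal_cutoff(roc_curve(f(scores), labels)), f(cut))
  expect_equal(auc(scores, 1 - labels), 1 - auc(scores, labels))
})

test_that("uninformative scores give an AUC near one half", {
  set.seed(55)
  scores <- rnorm(2000)
  labels <- rbinom(2000, 1, 0.3)
  expect_lt(abs(auc(scores, labels) - 0.5), 0.03)
})

test_that("Wald intervals have the textbook half-width and flag boundaries", {
  ci <- wald_ci(0.5, 100)
  expect_equal(unname(ci["upper"] - ci["lower"]) / 2, 0.098)
  expect_false(attr(ci, "boundary"))
  ci1 <- wald_ci(1.0, 50)
  expect_equal(as.numeric(ci1), c(1, 1))
  expect_true(attr(ci1, "boundary"))
  expect_equal(as.numeric(wald_ci(0, 10)), c(0, 0))
})

test_that("DeLong AUC and interval agree with the pROC implementation", {
  set.seed(202)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, plogis(scores - 0.5))
  dl <- delong_ci(scores, labels)
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(dl$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(dl$lower, ci[1], tolerance = 1e-9)
  expect_equal(dl$upper, ci[3], tolerance = 1e-9)
})

test_that("the bootstrap cutoff interval is seeded and reproducible", {
  set.seed(9)
  scores <- rnorm(400)
  labels <- rbinom(400, 1, plogis(2 * scores))
  a <- bootstrap_cutoff_ci(scores, labels, B = 200, seed = 11)
  b <- bootstrap_cutoff_ci(scores, labels, B = 200, seed = 11)
  expect_identical(a, b)
  c_ <- bootstrap_cutoff_ci(scores, labels, B = 200, seed = 12)
  expect_false(identical(a$lower, c_$lower) && identical(a$upper, c_$upper))
  expect_lte(a$lower, a$upper)
  expect_error(bootstrap_cutoff_ci(scores, labels, B = 50, seed = 1))
})

test_that("cutpoint assembles estimates, intervals and stability flags", {
  set.seed(14)
  scores <- rnorm(500)
  labels <- rbinom(500, 1, plogis(3 * scores))
  cp <- cutpoint(scores, labels, B = 200, seed = 3)
  expect_s3_class(cp, "cmets_cutpoint")
  expect_true(cp$sens >= 0 && cp$sens <= 1)
  expect_true(cp$auc_lo <= cp$auc && cp$auc <= cp$auc_hi)
  expect_true(cp$cutoff_lo <= cp$cutoff_hi)
  expect_false(cp$unstable)
  few_pos <- c(rnorm(200), rnorm(5, 3))
  few_lab <- c(rep(0, 200), rep(1, 5))
  cp2 <- cutpoint(few_pos, few_lab, B = 200, seed = 3)
  expect_true(cp2$unstable)
  expect_output(print(cp), "optimal cutoff")
})

test_that("stratified validation mirrors the 12-row report layout", {
  an <- cached_analysis()
  set.seed(1)
  co <- an$cohort[sample.int(nrow(an$cohort), 8000), ]
  val <- validate_cutoffs(co, B = 200, seed = 21)
  expect_equal(nrow(val), 12)
  expect_equal(sum(val$age_band == "7-18"), 3)
  expect_equal(val$group[val$age_band == "7-18"],
               c("male", "female", "total"))
  expect_true(all(val$auc > 0.5))
  # a single-class stratum yields an NA row and a warning
  co2 <- co
  co2$mets[co2$sex == "female" & co2$age < 11] <- FALSE
  expect_warning(val2 <- validate_cutoffs(co2, B = 200, seed = 21),
                 "single class")
  na_row <- val2[val2$age_band == "7-10" & val2$group == "female", ]
  expect_true(is.na(na_row$auc))
})
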