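#' Empirical ROC curve
#'
#' Builds the receiver operating characteristic curve for a continuous
#' score predicting a binary label, under the positivity rule
#' "positive if score >= threshold".  Operating points are evaluated at
#' every unique score value plus a `+Inf` sentinel, so the curve runs from
#' (sensitivity, specificity) = (1, 0) at the lowest threshold to (0, 1) at
#' the sentinel.
#'
#' @param scores Numeric vector, finite.
#' @param labels Binary vector (0/1 or logical); both classes must be
#'   present.
#' @return Object of class `roc_curve`: list with `thresholds` (ascending,
#'   last `Inf`), `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!length(scores) || any(!is.finite(scores)))
    stop("scores must be finite and non-empty")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos < 1 || n_neg < 1)
    stop("need at least one positive and one negative label")
  thr <- c(sort(unique(scores)), Inf)
  # counts of scores >= t, per class, via reverse cumulative sums
  pos_at <- tabulate(match(scores[labels == 1], thr), nbins = length(thr))
  neg_at <- tabulate(match(scores[labels == 0], thr), nbins = length(thr))
  tp <- rev(cumsum(rev(pos_at)))
  fp <- rev(cumsum(rev(neg_at)))
  structure(list(thresholds = thr, sensitivity = tp / n_pos,
                 specificity = 1 - fp / n_neg,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve:", length(x$thresholds) - 1, "unique thresholds,",
      x$n_pos, "positives,", x$n_neg, "negatives; AUC =",
      round(auc(x), 4), "\n")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Area under the ROC curve
#'
#' The AUC as the Mann-Whitney probability that a random positive scores
#' above a random negative, ties counted one half:
#' (concordant pairs + ties/2) / (n_pos * n_neg), computed from midranks.
#' `method = "trapezoid"` integrates the empirical ROC curve instead; the
#' two are mathematically identical and agree to machine precision.
#'
#' @param x A `roc_curve`, or a numeric score vector (then supply `labels`).
#' @param labels Binary labels when `x` is a score vector.
#' @param method `"mann-whitney"` (default) or `"trapezoid"`.
#' @return AUC as a proportion in [0, 1].
#' @export
#' @examples
#' auc(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 1
auc <- function(x, labels = NULL, method = c("mann-whitney", "trapezoid")) {
  method <- match.arg(method)
  if (inherits(x, "roc_curve")) {
    if (method == "trapezoid") return(auc_trapezoid(x))
    stop("Mann-Whitney AUC needs raw scores and labels; ",
         "use method = 'trapezoid' on a roc_curve")
  }
  scores <- x
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos < 1 || n_neg < 1)
    stop("need at least one positive and one negative label")
  if (method == "trapezoid") return(auc_trapezoid(roc_curve(scores, labels)))
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

auc_trapezoid <- function(roc) {
  fpr <- rev(1 - roc$specificity)  # ascending in fpr
  tpr <- rev(roc$sensitivity)
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Optimal score cutoff by maximum sensitivity + specificity
#'
#' Returns the threshold maximizing sensitivity + specificity (the Youden
#' criterion plus one).  When several thresholds attain the maximum, the
#' minimum threshold is returned.
#'
#' @param roc A `roc_curve`.
#' @return The optimal threshold (a score value).
#' @export
#' @examples
#' optimal_cutoff(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1)))  # 3
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  if (length(roc$thresholds) <= 2)
    stop("degenerate ROC curve: all scores tied")
  # compare sens + spec in exact integer arithmetic so that thresholds with
  # mathematically equal sums tie exactly and the minimum one is returned
  tp <- round(roc$sensitivity * roc$n_pos)
  tn <- round(roc$specificity * roc$n_neg)
  j <- tp * roc$n_neg + tn * roc$n_pos
  roc$thresholds[which.max(j)]  # which.max takes the first = smallest thr
}

#' Wald confidence interval for a proportion
#'
#' p +/- z * sqrt(p(1-p)/n), clipped to [0, 1].  At p = 0 or 1 the interval
#' degenerates to a point and is flagged as a boundary case.
#'
#' @param p Proportion estimate.
#' @param n Denominator.
#' @param z Normal quantile (default 1.96 for 95%).
#' @return Named vector `lower`, `upper`; attribute `boundary` is `TRUE`
#'   when p is 0 or 1.
#' @export
wald_ci <- function(p, n, z = 1.96) {
  half <- z * sqrt(p * (1 - p) / n)
  out <- c(lower = max(0, p - half), upper = min(1, p + half))
  attr(out, "boundary") <- p %in% c(0, 1)
  out
}

#' DeLong confidence interval for the AUC
#'
#' Variance of the Mann-Whitney AUC from positive and negative placement
#' values (DeLong's estimator); normal-approximation CI clipped to [0, 1].
#'
#' @param scores,labels As in [roc_curve()].
#' @param conf Confidence level (default 0.95).
#' @return List with `auc`, `se`, `lower`, `upper`.
#' @export
delong_ci <- function(scores, labels, conf = 0.95) {
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m < 1 || n < 1) stop("need both classes for the DeLong interval")
  # placements via midranks: V10_i = fraction of negatives below pos_i
  all_r <- rank(c(pos, neg))
  v10 <- (all_r[seq_len(m)] - rank(pos)) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - rank(neg)) / m
  a <- mean(v10)
  s2 <- if (m > 1) stats::var(v10) / m else 0
  s2 <- s2 + if (n > 1) stats::var(v01) / n else 0
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(s2)
  list(auc = a, se = se,
       lower = max(0, a - z * se), upper = min(1, a + z * se))
}

#' Bootstrap percentile CI for the optimal cutoff
#'
#' Resamples (score, label) pairs with replacement, re-runs the whole
#' cutoff-selection procedure on each resample and returns the percentile
#' interval of the resampled cutoffs.  Seeded and deterministic; resamples
#' that lose one of the classes are redrawn.
#'
#' @param scores,labels As in [roc_curve()].
#' @param B Number of bootstrap resamples (>= 200).
#' @param seed Integer seed (required for reproducibility).
#' @param conf Confidence level.
#' @return List with `lower`, `upper`, `B` and `unstable` (`TRUE` when
#'   fewer than 10 positives).
#' @export
bootstrap_cutoff_ci <- function(scores, labels, B = 1000, seed = 20150101,
                                conf = 0.95) {
  stopifnot(B >= 200)
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n <- length(scores)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(seed))
  cuts <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2 &&
          length(unique(scores[idx])) > 1) break
    }
    cuts[b] <- optimal_cutoff(roc_curve(scores[idx], labels[idx]))
  }
  alpha <- 1 - conf
  q <- stats::quantile(cuts, c(alpha / 2, 1 - alpha / 2), type = 7,
                       names = FALSE)
  list(lower = q[1], upper = q[2], B = B,
       unstable = sum(labels == 1) < 10)
}

#' Optimal cMetS cutoff with confidence intervals for one stratum
#'
#' Runs the full cutoff analysis on one set of scores and labels: ROC
#' curve, optimal cutoff (maximum sensitivity + specificity, minimum
#' threshold on ties), sensitivity and specificity at the cutoff with Wald
#' intervals, AUC with the DeLong interval, and a seeded percentile
#' bootstrap interval for the cutoff itself.
#'
#' @param scores,labels As in [roc_curve()].
#' @param B,seed,conf Bootstrap settings, see [bootstrap_cutoff_ci()].
#' @return Object of class `cmets_cutpoint`: one-row data.frame with
#'   `cutoff`, `cutoff_lo`, `cutoff_hi`, `sens`, `sens_lo`, `sens_hi`,
#'   `spec`, `spec_lo`, `spec_hi`, `auc`, `auc_lo`, `auc_hi`, `n_pos`,
#'   `n_neg`, `unstable`.
#' @export
cutpoint <- function(scores, labels, B = 1000, seed = 20150101,
                     conf = 0.95) {
  roc <- roc_curve(scores, labels)
  cut <- optimal_cutoff(roc)
  i <- match(cut, roc$thresholds)
  sens <- roc$sensitivity[i]; spec <- roc$specificity[i]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  sci <- wald_ci(sens, roc$n_pos, z = z)
  pci <- wald_ci(spec, roc$n_neg, z = z)
  dl <- delong_ci(scores, labels, conf = conf)
  bt <- bootstrap_cutoff_ci(scores, labels, B = B, seed = seed, conf = conf)
  out <- data.frame(cutoff = cut, cutoff_lo = bt$lower,
                    cutoff_hi = bt$upper,
                    sens = sens, sens_lo = sci["lower"],
                    sens_hi = sci["upper"],
                    spec = spec, spec_lo = pci["lower"],
                    spec_hi = pci["upper"],
                    auc = dl$auc, auc_lo = dl$lower, auc_hi = dl$upper,
                    n_pos = roc$n_pos, n_neg = roc$n_neg,
                    unstable = bt$unstable, row.names = NULL)
  class(out) <- c("cmets_cutpoint", "data.frame")
  out
}

#' @export
print.cmets_cutpoint <- function(x, ...) {
  cat(sprintf(
    "optimal cutoff %.2f (95%% CI %.2f-%.2f); sens %.0f%% (%.0f-%.0f), spec %.0f%% (%.0f-%.0f), AUC %.0f%% (%.0f-%.0f)\n",
    x$cutoff, x$cutoff_lo, x$cutoff_hi, 100 * x$sens, 100 * x$sens_lo,
    100 * x$sens_hi, 100 * x$spec, 100 * x$spec_lo, 100 * x$spec_hi,
    100 * x$auc, 100 * x$auc_lo, 100 * x$auc_hi))
  if (isTRUE(x$unstable))
    cat("  (fewer than 10 positives: bootstrap interval unstable)\n")
  invisible(x)
}

#' Stratified cMetS cutoff validation
#'
#' Derives optimal cMetS cutoffs with sensitivity, specificity, AUC and
#' 95% confidence intervals in twelve strata mirroring the standard report
#' layout: boys, girls and total within each age band (7-10, 11-14, 15-18),
#' plus boys, girls and total over the full 7-18 range.
#'
#' @param data data.frame with `age`, `sex`, a score column and a logical
#'   label column.
#' @param score_col,label_col Column names (defaults `"cmets"`, `"mets"`).
#' @param B,seed,conf Bootstrap settings per stratum, see
#'   [bootstrap_cutoff_ci()].
#' @return Object of class `cmets_validation`: data.frame with `age_band`
#'   and `group` columns followed by the [cutpoint()] columns.  Strata with
#'   a single class yield `NA` estimates and a warning.
#' @export
#' @examples
#' \donttest{
#' co <- classify_mets(simulate_cohort(5000, seed = 3),
#'                     mets_criteria("table_footnote"))
#' co$cmets <- fitted(cmets(co))
#' validate_cutoffs(co, B = 200)
#' }
validate_cutoffs <- function(data, score_col = "cmets", label_col = "mets",
                             B = 1000, seed = 20150101, conf = 0.95) {
  stopifnot(all(c(score_col, label_col, "age", "sex") %in% names(data)))
  band <- as.character(age_band(data$age))
  strata <- rbind(
    expand.grid(age_band = age_band_levels(),
                group = c("male", "female", "total"),
                stringsAsFactors = FALSE)[order(rep(1:3, 3)), ],
    data.frame(age_band = "7-18", group = c("male", "female", "total")))
  na_row <- cutpoint(c(0, 1), c(0, 1), B = 200, seed = 1)
  na_row[1, ] <- NA
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sel <- (strata$age_band[i] == "7-18" | band == strata$age_band[i]) &
      (strata$group[i] == "total" | data$sex == strata$group[i])
    sc <- data[[score_col]][sel]; lb <- data[[label_col]][sel]
    ok <- !is.na(sc) & !is.na(lb)
    if (length(unique(lb[ok])) < 2) {
      warning("stratum ", strata$age_band[i], "/", strata$group[i],
              " has a single class; estimates set to NA")
      return(na_row)
    }
    cutpoint(sc[ok], lb[ok], B = B, seed = seed, conf = conf)
  }))
  out <- cbind(strata, out)
  rownames(out) <- NULL
  class(out) <- c("cmets_validation", "data.frame")
  out
}

#' @export
print.cmets_validation <- function(x, digits = 2, ...) {
  cat("cMetS cutoff validation (max sensitivity + specificity)\n")
  shown <- data.frame(
    stratum = paste(x$age_band, x$group),
    cutoff = sprintf("%.2f (%.2f-%.2f)", x$cutoff, x$cutoff_lo, x$cutoff_hi),
    sensitivity = sprintf("%.0f (%.0f-%.0f)", 100 * x$sens, 100 * x$sens_lo,
                          100 * x$sens_hi),
    specificity = sprintf("%.0f (%.0f-%.0f)", 100 * x$spec, 100 * x$spec_lo,
                          100 * x$spec_hi),
    AUC = sprintf("%.0f (%.0f-%.0f)", 100 * x$auc, 100 * x$auc_lo,
                  100 * x$auc_hi))
  print(shown, row.names = FALSE)
  invisible(x)
}
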