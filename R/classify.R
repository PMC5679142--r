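#' Flag MetS components and the binary MetS label
#'
#' Applies a modified ATP-III criteria set (see [mets_criteria()]) to a
#' cohort, producing the five component flags, the component count and the
#' binary MetS label.  Elevated blood pressure is flagged when SBP or DBP
#' exceeds (strictly) the configured percentile for the subject's sex, age
#' and height cell; the abdominal rule is either waist-to-height ratio > 0.5
#' or waist above the sex/age percentile, per the preset.
#'
#' Subjects with any required measurement missing, or whose percentile cell
#' cannot be resolved, are retained in the output with `NA` flags and are
#' counted in the `exclusions` attribute (complete-case downstream).
#'
#' @param cohort Subject-level data.frame; derived columns are added if
#'   absent.
#' @param criteria A [mets_criteria()] object.
#' @param reference A `percentile_reference`; by default an empirical
#'   within-cohort reference is fitted at the criteria's percentile level.
#' @param min_bin Minimum bin size for the default empirical reference.
#' @return The cohort with logical columns `high_tg`, `low_hdl`, `high_fbg`,
#'   `abdominal_obesity`, `elevated_sbp`, `elevated_dbp`, `elevated_bp`,
#'   integer `n_components` and logical `mets` appended.  Attribute
#'   `exclusions` holds the number of unevaluable subjects.
#' @export
#' @examples
#' co <- simulate_cohort(2000, seed = 42)
#' cl <- classify_mets(co, mets_criteria("table_footnote"))
#' table(cl$n_components)
classify_mets <- function(cohort, criteria = mets_criteria(),
                          reference = NULL, min_bin = 20) {
  stopifnot(inherits(criteria, "mets_criteria"))
  cohort <- add_derived(check_cohort(cohort))
  if (is.null(reference))
    reference <- empirical_reference(cohort, level = criteria$bp_level,
                                     min_bin = min_bin)
  pct <- lookup_reference(reference, cohort$sex, cohort$age, cohort$height)

  cohort$high_tg <- apply_cmp(cohort$tg, criteria$tg$op, criteria$tg$value)
  hdl_cut <- rep(criteria$hdl$value, nrow(cohort))
  if (!is.null(criteria$hdl$male_15_18)) {
    older_boy <- cohort$sex == "male" & !is.na(cohort$age) &
      cohort$age >= 15 & cohort$age < 19
    hdl_cut[older_boy] <- criteria$hdl$male_15_18
  }
  cohort$low_hdl <- apply_cmp(cohort$hdl, criteria$hdl$op, hdl_cut)
  cohort$high_fbg <- apply_cmp(cohort$fbg, criteria$fbg$op,
                               criteria$fbg$value)
  cohort$abdominal_obesity <- if (criteria$abdominal == "whtr_gt_0.5") {
    cohort$whtr > 0.5
  } else {
    cohort$waist > pct$wc_p
  }
  cohort$elevated_sbp <- cohort$sbp > pct$sbp_p
  cohort$elevated_dbp <- cohort$dbp > pct$dbp_p
  cohort$elevated_bp <- cohort$elevated_sbp | cohort$elevated_dbp

  flags <- cbind(cohort$high_tg, cohort$low_hdl, cohort$high_fbg,
                 cohort$abdominal_obesity, cohort$elevated_bp)
  cohort$n_components <- as.integer(rowSums(flags))
  cohort$mets <- cohort$n_components >= criteria$min_components
  n_excl <- sum(is.na(cohort$n_components))
  if (n_excl > 0)
    message(n_excl, " subject(s) unevaluable (missing measurements); ",
            "flags set to NA")
  attr(cohort, "exclusions") <- n_excl
  attr(cohort, "criteria") <- criteria
  cohort
}

#' Secondary cardiometabolic flags
#'
#' Flags overweight (BMI between the 85th and 95th empirical percentile for
#' sex and age), obesity (BMI above the 95th percentile), high LDL
#' (> 110 mg/dL) and high total cholesterol (> 200 mg/dL).  Overweight and
#' obese are mutually exclusive.
#'
#' @inheritParams classify_mets
#' @return The cohort with logical columns `overweight`, `obese`,
#'   `high_ldl`, `high_tc` appended.
#' @export
secondary_flags <- function(cohort, reference = NULL, min_bin = 20) {
  cohort <- add_derived(check_cohort(cohort))
  if (is.null(reference))
    reference <- empirical_reference(cohort, min_bin = min_bin)
  pct <- lookup_reference(reference, cohort$sex, cohort$age, cohort$height)
  cohort$obese <- cohort$bmi > pct$bmi_p95
  cohort$overweight <- cohort$bmi > pct$bmi_p85 & !cohort$obese
  cohort$high_ldl <- cohort$ldl > 110
  cohort$high_tc <- cohort$tc > 200
  cohort
}
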