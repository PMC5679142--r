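#' Published stratum summary statistics for 7-18-year-olds
#'
#' Mean and standard deviation of ten anthropometric and biochemical
#' measurements in six sex-by-age strata (male/female crossed with age bands
#' 7-10, 11-14 and 15-18 years), as printed by a national school-based health
#' survey of children and adolescents.  These constants are the default
#' calibration targets of [simulate_cohort()]: a cohort generated with them
#' has stratum means and SDs matching the published table.
#'
#' Units: weight kg; height and waist cm; sbp and dbp mmHg; fbg, tg, tc, hdl
#' and ldl mg/dL.
#'
#' @return A data.frame with 6 rows (one per stratum) and columns `sex`
#'   (`"male"`/`"female"`), `age_band` (`"7-10"`, `"11-14"`, `"15-18"`) and,
#'   for each measurement `<m>`, `<m>_mean` and `<m>_sd`.
#' @seealso [simulate_cohort()], [reference_bp_rows()]
#' @export
#' @examples
#' ref <- reference_strata()
#' subset(ref, sex == "male" & age_band == "7-10", c(sbp_mean, sbp_sd))
reference_strata <- function() {
  # columns: mean, sd per measure; rows below are (male, female) x band
  tab <- rbind(
    # 7-10 years
    c(28.36, 9.56, 130.87, 10.50, 60.03, 9.54, 93.85, 12.69, 60.63, 10.31,
      92.31, 17.26, 86.78, 49.06, 155.43, 29.37, 47.59, 10.80, 90.48, 23.46),
    c(27.06, 7.95, 129.27, 9.75, 59.09, 8.53, 94.12, 12.74, 61.00, 10.39,
      91.05, 9.83, 87.45, 42.09, 154.03, 29.06, 46.59, 10.38, 89.95, 24.75),
    # 11-14 years
    c(41.43, 13.60, 148.43, 12.25, 67.68, 11.25, 99.16, 12.61, 63.93, 10.20,
      92.18, 10.45, 85.67, 41.60, 153.29, 27.21, 46.59, 10.06, 89.56, 22.72),
    c(42.68, 12.56, 149.28, 11.28, 67.25, 11.11, 99.71, 12.03, 63.95, 9.74,
      91.33, 12.16, 89.96, 47.01, 154.89, 25.30, 45.46, 9.38, 91.43, 20.53),
    # 15-18 years
    c(59.75, 16.83, 167.71, 13.54, 76.38, 12.76, 106.55, 12.09, 68.21, 10.38,
      91.66, 11.17, 89.59, 47.29, 150.18, 27.78, 44.39, 9.45, 87.87, 22.56),
    c(55.31, 13.27, 159.80, 8.93, 72.68, 10.00, 103.76, 11.47, 66.57, 9.48,
      91.14, 10.82, 89.38, 44.07, 155.75, 25.82, 46.86, 9.49, 91.02, 21.84)
  )
  measures <- cohort_measures()
  colnames(tab) <- as.vector(t(outer(measures, c("mean", "sd"), paste,
                                     sep = "_")))
  out <- data.frame(
    sex = rep(c("male", "female"), 3),
    age_band = rep(c("7-10", "11-14", "15-18"), each = 2),
    tab,
    stringsAsFactors = FALSE
  )
  stopifnot(all(tab > 0))
  out
}

#' Published group-level blood-pressure means
#'
#' Printed group means of SBP, DBP and MAP (mmHg) from the same published
#' summary table as [reference_strata()], for the rows where the printed MAP
#' is exactly the MAP of the printed SBP/DBP means at two decimals.  Because
#' MAP is linear in SBP and DBP, the MAP of group means equals the group mean
#' of MAP; these rows provide a closed-form consistency check of
#' [mean_arterial_pressure()].
#'
#' @return A data.frame with columns `age_band`, `group`
#'   (`"total"`/`"male"`/`"female"`), `sbp_mean`, `dbp_mean`, `map_mean`.
#' @seealso [mean_arterial_pressure()]
#' @export
reference_bp_rows <- function() {
  data.frame(
    age_band = c("7-10", "7-10", "7-10", "11-14", "11-14", "7-18"),
    group    = c("total", "male", "female", "total", "female", "total"),
    sbp_mean = c(93.99, 93.85, 94.12, 99.43, 99.71, 99.17),
    dbp_mean = c(60.82, 60.63, 61.00, 63.94, 63.95, 63.83),
    map_mean = c(71.88, 71.70, 72.04, 75.77, 75.87, 75.61),
    stringsAsFactors = FALSE
  )
}

# Measurement columns of a subject table, in canonical order.
cohort_measures <- function() {
  c("weight", "height", "waist", "sbp", "dbp", "fbg", "tg", "tc", "hdl", "ldl")
}

#' Age bands used throughout the analysis
#'
#' Cuts continuous age in years into the three bands `7-10`, `11-14` and
#' `15-18` (intervals [7,11), [11,15), [15,19)).
#'
#' @param age Numeric vector of ages in years, in [7, 19).
#' @return A factor with levels `"7-10"`, `"11-14"`, `"15-18"`.
#' @export
#' @examples
#' age_band(c(7, 10.9, 11, 18.9))
age_band <- function(age) {
  stopifnot(is.numeric(age))
  if (any(!is.na(age) & (age < 7 | age >= 19)))
    stop("age must be within [7, 19) years")
  cut(age, breaks = c(7, 11, 15, 19), labels = c("7-10", "11-14", "15-18"),
      right = FALSE)
}

age_band_levels <- function() c("7-10", "11-14", "15-18")

age_band_midpoint <- function(band) {
  mids <- c("7-10" = 9, "11-14" = 13, "15-18" = 17)
  unname(mids[as.character(band)])
}

# Validate a subject-level cohort table; returns it with sex normalised.
check_cohort <- function(cohort, require_measures = cohort_measures()) {
  if (!is.data.frame(cohort)) stop("cohort must be a data.frame")
  needed <- c("age", "sex", require_measures)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  cohort$sex <- as.character(cohort$sex)
  bad_sex <- !cohort$sex %in% c("male", "female") & !is.na(cohort$sex)
  if (any(bad_sex))
    stop("sex must be 'male' or 'female'")
  cohort
}
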