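#' Mean arterial pressure
#'
#' MAP = (SBP - DBP)/3 + DBP, i.e. diastolic pressure plus one third of the
#' pulse pressure.  Vectorised; no rounding is applied (round only when
#' rendering tables).
#'
#' @param sbp Systolic blood pressure, mmHg.
#' @param dbp Diastolic blood pressure, mmHg; must satisfy `0 < dbp < sbp`.
#' @return MAP in mmHg, strictly between `dbp` and `sbp`.
#' @export
#' @examples
#' mean_arterial_pressure(93.99, 60.82)  # 71.88 at 2 dp
mean_arterial_pressure <- function(sbp, dbp) {
  stopifnot(is.numeric(sbp), is.numeric(dbp))
  ok <- is.na(sbp) | is.na(dbp) | (sbp > dbp & dbp > 0)
  if (!all(ok))
    stop("inconsistent blood pressure reading: need sbp > dbp > 0")
  (sbp - dbp) / 3 + dbp
}

#' Body mass index
#'
#' Weight in kilograms divided by the square of height in metres.  Height is
#' accepted in centimetres (the unit in which pediatric survey tables print
#' it) and converted internally.
#'
#' @param weight Weight in kg, positive.
#' @param height Height in cm, positive.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(60, 150)  # 26.67
bmi <- function(weight, height) {
  stopifnot(is.numeric(weight), is.numeric(height))
  if (any(weight <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE))
    stop("weight and height must be positive")
  weight / (height / 100)^2
}

#' Waist-to-height ratio
#'
#' Waist circumference divided by height, both in the same unit (cm).
#' Values above 0.5 flag abdominal obesity under the waist-to-height
#' criterion.
#'
#' @param waist Waist circumference in cm, positive.
#' @param height Height in cm, positive.
#' @return Dimensionless ratio.
#' @export
#' @examples
#' waist_height_ratio(60, 120)  # 0.5
waist_height_ratio <- function(waist, height) {
  stopifnot(is.numeric(waist), is.numeric(height))
  if (any(waist <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE))
    stop("waist and height must be positive")
  waist / height
}

#' Add derived physiologic measures to a cohort table
#'
#' Appends `map` (mean arterial pressure, mmHg), `bmi` (kg/m^2) and `whtr`
#' (waist-to-height ratio) columns computed from the raw measurement columns.
#' Existing columns of those names are overwritten.
#'
#' @param cohort A subject-level data.frame with columns `sbp`, `dbp`,
#'   `weight`, `height`, `waist` (see [simulate_cohort()] for the full
#'   schema).
#' @return `cohort` with `map`, `bmi` and `whtr` columns appended.
#' @export
add_derived <- function(cohort) {
  cohort <- check_cohort(cohort,
                         require_measures = c("weight", "height", "waist",
                                              "sbp", "dbp"))
  cohort$map <- mean_arterial_pressure(cohort$sbp, cohort$dbp)
  cohort$bmi <- bmi(cohort$weight, cohort$height)
  cohort$whtr <- waist_height_ratio(cohort$waist, cohort$height)
  cohort
}
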