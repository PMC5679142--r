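#' Modified ATP-III criteria presets for pediatric metabolic syndrome
#'
#' Returns a criteria configuration defining the five MetS components.  Two
#' named presets are provided, reflecting the two threshold sets in common
#' use for 7-18-year-olds:
#' \describe{
#'   \item{`methods_text`}{TG >= 150 mg/dL; HDL-C <= 40 mg/dL;
#'     FBG >= 100 mg/dL; abdominal obesity as waist-to-height ratio > 0.5;
#'     elevated BP as SBP or DBP above the 90th percentile for age, sex and
#'     height.}
#'   \item{`table_footnote`}{TG > 100 mg/dL; HDL-C < 40 mg/dL (boys in the
#'     15-18 band: < 45 mg/dL); FBG > 100 mg/dL; abdominal obesity as waist
#'     circumference above the 90th percentile for age and sex; elevated BP
#'     as above.}
#' }
#' MetS is flagged when at least `min_components` (default 3) of the five
#' components are present.  Comparators are applied exactly as stated
#' (strict vs inclusive).
#'
#' @param preset `"methods_text"` (default) or `"table_footnote"`.
#' @param min_components Minimum number of abnormal components for MetS.
#' @param bp_level Percentile level (0-100) of the blood pressure rule.
#' @return An object of class `mets_criteria`.
#' @export
#' @examples
#' mets_criteria("table_footnote")
mets_criteria <- function(preset = c("methods_text", "table_footnote"),
                          min_components = 3, bp_level = 90) {
  preset <- match.arg(preset)
  stopifnot(min_components >= 1, min_components <= 5,
            bp_level > 0, bp_level < 100)
  cfg <- if (preset == "methods_text") {
    list(
      preset = preset,
      tg = list(op = ">=", value = 150),
      hdl = list(op = "<=", value = 40, male_15_18 = NULL),
      fbg = list(op = ">=", value = 100),
      abdominal = "whtr_gt_0.5",
      bp_level = bp_level,
      min_components = min_components
    )
  } else {
    list(
      preset = preset,
      tg = list(op = ">", value = 100),
      hdl = list(op = "<", value = 40, male_15_18 = 45),
      fbg = list(op = ">", value = 100),
      abdominal = "wc_gt_pct",
      bp_level = bp_level,
      min_components = min_components
    )
  }
  structure(cfg, class = "mets_criteria")
}

#' @export
print.mets_criteria <- function(x, ...) {
  cat("Pediatric MetS criteria (modified ATP-III), preset:", x$preset, "\n")
  cat("  high TG : TG", x$tg$op, x$tg$value, "mg/dL\n")
  cat("  low HDL : HDL", x$hdl$op, x$hdl$value, "mg/dL")
  if (!is.null(x$hdl$male_15_18))
    cat(" (boys 15-18:", x$hdl$op, x$hdl$male_15_18, "mg/dL)")
  cat("\n  high FBG: FBG", x$fbg$op, x$fbg$value, "mg/dL\n")
  cat("  abdominal obesity:",
      if (x$abdominal == "whtr_gt_0.5") "waist/height > 0.5"
      else sprintf("waist > %gth percentile (sex, age)", x$bp_level), "\n")
  cat(sprintf("  elevated BP: SBP or DBP > %gth percentile (sex, age, height)\n",
              x$bp_level))
  cat("  MetS: >=", x$min_components, "components\n")
  invisible(x)
}

#' Serialize criteria to and from YAML
#'
#' @param criteria A [mets_criteria()] object.
#' @param path File path.
#' @return `read_criteria` returns a `mets_criteria` object.
#' @export
write_criteria <- function(criteria, path) {
  stopifnot(inherits(criteria, "mets_criteria"))
  yaml::write_yaml(unclass(criteria), path)
  invisible(path)
}

#' @rdname write_criteria
#' @export
read_criteria <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- mets_criteria(cfg$preset,
                        min_components = cfg$min_components,
                        bp_level = cfg$bp_level)
  for (f in c("tg", "hdl", "fbg"))
    base[[f]] <- utils::modifyList(base[[f]], cfg[[f]])
  base$abdominal <- cfg$abdominal
  base
}

# Apply a comparator string to a numeric vector.
apply_cmp <- function(x, op, value) {
  switch(op,
         ">"  = x > value,
         ">=" = x >= value,
         "<"  = x < value,
         "<=" = x <= value,
         stop("unknown comparator: ", op))
}
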