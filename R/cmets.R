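#' Fit an age/sex standardization model for one component
#'
#' Ordinary least-squares regression of one cardiometabolic component on age
#' and sex, used to produce age/sex-adjusted residual z-scores.  Three
#' covariate specifications are supported: `pooled_age_sex` (intercept +
#' continuous age + sex indicator, the default), `by_sex_age` (separate
#' age regressions per sex) and `pooled_age_sex_interaction` (adds the
#' age-by-sex interaction).
#'
#' The residual standard deviation uses the n - p denominator (the usual
#' OLS convention), where p counts the fitted coefficients.
#'
#' @param data data.frame with the component column plus `age` and `sex`.
#' @param component Name of the component column (e.g. `"waist"`, `"map"`,
#'   `"hdl"`, `"tg"`, `"fbg"`).
#' @param covariate_spec One of `"pooled_age_sex"`, `"by_sex_age"`,
#'   `"pooled_age_sex_interaction"`.
#' @return An object of class `zscore_model` with elements `component`,
#'   `covariate_spec`, `coefficients` (per sex, for the stratified spec),
#'   `residual_sd` and `n_fit`.
#' @seealso [standardize()], [cmets()]
#' @export
fit_zscore_model <- function(data, component,
                             covariate_spec = c("pooled_age_sex",
                                                "by_sex_age",
                                                "pooled_age_sex_interaction")) {
  covariate_spec <- match.arg(covariate_spec)
  if (!component %in% names(data))
    stop("component column not found: ", component)
  d <- data.frame(y = data[[component]], age = data$age,
                  sex = as.character(data$sex))
  d <- d[stats::complete.cases(d), ]
  form <- switch(covariate_spec,
                 pooled_age_sex = y ~ age + sex,
                 by_sex_age = y ~ age,
                 pooled_age_sex_interaction = y ~ age * sex)
  fit_one <- function(dd) {
    p <- length(attr(stats::terms(form), "term.labels")) + 1
    if (nrow(dd) < p + 2) stop("insufficient observations to fit ", component)
    if (stats::var(dd$y) == 0)
      stop("degenerate fit for ", component, ": constant response")
    fit <- stats::lm(form, data = dd)
    if (any(is.na(stats::coef(fit)))) stop("singular design for ", component)
    s <- summary(fit)$sigma  # n - p denominator
    if (!is.finite(s) || s <= 1e-10 * stats::sd(dd$y))
      stop("degenerate fit for ", component, ": zero residual variance")
    list(coefficients = stats::coef(fit), residual_sd = s, n = nrow(dd))
  }
  fits <- if (covariate_spec == "by_sex_age") {
    lapply(split(d, d$sex), fit_one)
  } else {
    list(pooled = fit_one(d))
  }
  structure(list(component = component, covariate_spec = covariate_spec,
                 fits = fits, n_fit = nrow(d)),
            class = "zscore_model")
}

#' @export
print.zscore_model <- function(x, ...) {
  cat("z-score model for", x$component, "(", x$covariate_spec, ", n =",
      x$n_fit, ")\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(" ", nm, ": ",
        paste(names(f$coefficients), signif(f$coefficients, 5),
              sep = " = ", collapse = ", "),
        "; residual SD = ", signif(f$residual_sd, 5), "\n", sep = "")
  }
  invisible(x)
}

# Predicted component mean for given covariates.
predict_zscore_model <- function(model, age, sex) {
  sex <- as.character(sex)
  n <- length(age)
  pred <- rep(NA_real_, n)
  if (model$covariate_spec == "by_sex_age") {
    for (s in names(model$fits)) {
      b <- model$fits[[s]]$coefficients
      sel <- sex == s
      pred[sel] <- b["(Intercept)"] + b["age"] * age[sel]
    }
  } else {
    b <- model$fits$pooled$coefficients
    male <- as.numeric(sex == "male")
    pred <- b["(Intercept)"] + b["age"] * age +
      ifelse(is.na(b["sexmale"]), 0, b["sexmale"]) * male
    if ("age:sexmale" %in% names(b))
      pred <- pred + b["age:sexmale"] * age * male
  }
  unname(pred)
}

#' Standardized residual (z-score) of an observation
#'
#' z = (observed - predicted) / residual SD under a fitted
#' [fit_zscore_model()] model.
#'
#' @param model A `zscore_model`.
#' @param observed Observed component value(s).
#' @param age,sex Covariates of the observation(s).
#' @return Dimensionless z-score vector.
#' @export
standardize <- function(model, observed, age, sex) {
  stopifnot(inherits(model, "zscore_model"))
  pred <- predict_zscore_model(model, age, sex)
  sd_vec <- if (model$covariate_spec == "by_sex_age") {
    vapply(as.character(sex), function(s) model$fits[[s]]$residual_sd,
           numeric(1))
  } else {
    model$fits$pooled$residual_sd
  }
  (observed - pred) / sd_vec
}

#' Continuous metabolic syndrome score
#'
#' Fits, for each of the five MetS components — waist circumference, mean
#' arterial pressure, HDL cholesterol, triglycerides and fasting glucose —
#' an ordinary least-squares regression on age and sex, standardizes the
#' residuals to z-scores, multiplies the HDL z-score by -1 (HDL is
#' inversely related to metabolic risk) and sums the five z-scores into the
#' continuous MetS score (cMetS).  A higher score indicates a less
#' favorable metabolic profile.
#'
#' The score is sample-specific: models are fitted on, and by construction
#' centred within, the analysis sample.  On the fitting sample each z-score
#' has mean exactly 0 and, with the n - p residual-SD convention, unit
#' scale; the score itself has mean 0.  Applying a fitted object to new
#' data (via [predict.cmets()]) emits a warning, since cutoffs derived from
#' one population do not transfer without revalidation.
#'
#' @param data Subject-level data.frame with columns `waist`, `hdl`, `tg`,
#'   `fbg`, `age`, `sex` and either `map` or the `sbp`/`dbp` pair (MAP is
#'   derived if absent).  Subjects with any of these missing are excluded
#'   (count reported in the fitted object).
#' @param covariate_spec Covariate design passed to [fit_zscore_model()].
#' @param log_tg If `TRUE`, triglycerides are log-transformed before
#'   regression (sensitivity analysis; default `FALSE`).
#' @return An object of class `cmets`: a list with `models` (five
#'   `zscore_model`s), `z` (data.frame of `z_waist`, `z_map`, `z_hdl`,
#'   `z_tg`, `z_fbg`, HDL already sign-flipped), `score` (the cMetS vector,
#'   `NA` for excluded subjects), `id`, `n`, `n_excluded`, `covariate_spec`,
#'   `log_tg` and `call`.
#' @export
#' @examples
#' co <- simulate_cohort(1000, seed = 7)
#' fit <- cmets(co)
#' print(fit)
#' head(fitted(fit))
cmets <- function(data, covariate_spec = c("pooled_age_sex", "by_sex_age",
                                           "pooled_age_sex_interaction"),
                  log_tg = FALSE) {
  covariate_spec <- match.arg(covariate_spec)
  data <- check_cohort(data, require_measures = c("waist", "hdl", "tg",
                                                  "fbg"))
  if (!"map" %in% names(data)) {
    if (!all(c("sbp", "dbp") %in% names(data)))
      stop("need either a map column or sbp and dbp")
    data$map <- mean_arterial_pressure(data$sbp, data$dbp)
  }
  if (log_tg) data$log_tg <- log(data$tg)
  comps <- c(waist = "waist", map = "map", hdl = "hdl",
             tg = if (log_tg) "log_tg" else "tg", fbg = "fbg")
  used <- stats::complete.cases(data[, c(unname(comps), "age", "sex")])
  n_excl <- sum(!used)
  if (sum(used) == 0) stop("no complete cases to fit cMetS models")
  fit_data <- data[used, ]
  models <- lapply(comps, function(cc)
    fit_zscore_model(fit_data, cc, covariate_spec))
  z <- as.data.frame(lapply(models, function(m)
    standardize(m, fit_data[[m$component]], fit_data$age, fit_data$sex)))
  names(z) <- paste0("z_", names(comps))
  z$z_hdl <- -z$z_hdl
  score <- rep(NA_real_, nrow(data))
  score[used] <- rowSums(z)
  structure(list(models = models, z = z, score = score, used = used,
                 id = if ("id" %in% names(data)) data$id else
                   seq_len(nrow(data)),
                 n = sum(used), n_excluded = n_excl,
                 covariate_spec = covariate_spec, log_tg = log_tg,
                 call = match.call()),
            class = "cmets")
}

#' @export
print.cmets <- function(x, ...) {
  cat("Continuous metabolic syndrome score (cMetS)\n")
  cat("  components: waist, MAP, HDL (sign-flipped),",
      if (x$log_tg) "log(TG)," else "TG,", "FBG\n")
  cat("  covariate specification:", x$covariate_spec, "\n")
  cat("  n =", x$n, "fitted;", x$n_excluded, "excluded (incomplete)\n")
  sc <- x$score[x$used]
  cat(sprintf("  score: mean %.3g, SD %.3f, range [%.2f, %.2f]\n",
              mean(sc), stats::sd(sc), min(sc), max(sc)))
  invisible(x)
}

#' @describeIn cmets Coefficient matrix (components x terms) of the five
#'   standardization regressions; for the sex-stratified specification, one
#'   row per component and sex.
#' @param object,x A fitted `cmets` object.
#' @param ... Unused.
#' @export
coef.cmets <- function(object, ...) {
  rows <- list()
  for (m in object$models) {
    for (nm in names(m$fits)) {
      f <- m$fits[[nm]]
      lab <- if (nm == "pooled") m$component else paste(m$component, nm,
                                                       sep = ".")
      rows[[lab]] <- c(f$coefficients, residual_sd = f$residual_sd)
    }
  }
  terms <- unique(unlist(lapply(rows, names)))
  out <- t(vapply(rows, function(r) r[terms], numeric(length(terms))))
  colnames(out) <- terms
  out
}

#' @describeIn cmets Summary: per-component coefficients, residual SDs and
#'   the score distribution.
#' @export
summary.cmets <- function(object, ...) {
  structure(list(coef = coef.cmets(object),
                 n = object$n, n_excluded = object$n_excluded,
                 covariate_spec = object$covariate_spec,
                 score_summary = summary(object$score[object$used]),
                 score_sd = stats::sd(object$score[object$used])),
            class = "summary.cmets")
}

#' @export
print.summary.cmets <- function(x, ...) {
  cat("cMetS standardization models (", x$covariate_spec, ", n = ", x$n,
      ", excluded = ", x$n_excluded, ")\n\n", sep = "")
  print(round(x$coef, 4))
  cat("\nScore distribution:\n")
  print(x$score_summary)
  cat("SD:", round(x$score_sd, 4), "\n")
  invisible(x)
}

#' @describeIn cmets Fitted cMetS scores of the analysis sample (`NA` for
#'   excluded subjects).
#' @export
fitted.cmets <- function(object, ...) object$score

#' @describeIn cmets Matrix of component z-scores (HDL sign-flipped) for
#'   the fitting sample.
#' @export
residuals.cmets <- function(object, ...) as.matrix(object$z)

#' Score new subjects with fitted cMetS models
#'
#' Applies the five fitted standardization regressions to `newdata` and
#' returns component z-scores and the aggregated cMetS score.  Because the
#' score is standardized within the fitting sample, scoring a different
#' cohort emits a sample-specific warning.
#'
#' @param object A fitted [cmets()] object.
#' @param newdata Optional data.frame with the same measurement columns; if
#'   omitted, the fitting-sample scores are returned.
#' @param ... Unused.
#' @return With `newdata`: a data.frame of `z_*` columns and `cmets`.
#'   Without: the fitted score vector.
#' @export
predict.cmets <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$score)
  warning("cMetS is sample-specific: scores for new data are standardized ",
          "by the fitting sample's regressions and need revalidation")
  if (object$log_tg) newdata$log_tg <- log(newdata$tg)
  if (!"map" %in% names(newdata) && all(c("sbp", "dbp") %in% names(newdata)))
    newdata$map <- mean_arterial_pressure(newdata$sbp, newdata$dbp)
  z <- as.data.frame(lapply(object$models, function(m)
    standardize(m, newdata[[m$component]], newdata$age, newdata$sex)))
  names(z) <- paste0("z_", names(object$models))
  z$z_hdl <- -z$z_hdl
  z$cmets <- rowSums(z)
  z
}

#' @describeIn cmets Histogram of the score with a rug of component-count
#'   group means when `groups` is supplied.
#' @param groups Optional integer vector (component counts) aligned with the
#'   fitted subjects, used to overlay group means.
#' @export
plot.cmets <- function(x, groups = NULL, ...) {
  sc <- x$score[x$used]
  graphics::hist(sc, breaks = 50, freq = FALSE, main = "cMetS score",
                 xlab = "cMetS (sum of z-scores)", col = "grey85",
                 border = "white", ...)
  if (!is.null(groups)) {
    gm <- tapply(sc, groups[x$used], mean)
    graphics::abline(v = gm, col = "firebrick", lwd = 2)
    graphics::mtext(paste("group means:",
                          paste(names(gm), round(gm, 2), sep = "=",
                                collapse = ", ")),
                    side = 3, line = 0, cex = 0.8)
  }
  invisible(x)
}

#' Serialize fitted cMetS models to JSON
#'
#' Writes component, covariate specification, coefficients, residual SD and
#' fitting n for each of the five standardization models.
#'
#' @param object A fitted [cmets()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cmets_models <- function(object, path) {
  stopifnot(inherits(object, "cmets"))
  payload <- lapply(object$models, function(m) {
    list(component = m$component, covariate_spec = m$covariate_spec,
         n_fit = m$n_fit,
         fits = lapply(m$fits, function(f)
           list(coefficients = as.list(f$coefficients),
                residual_sd = f$residual_sd, n = f$n)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
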