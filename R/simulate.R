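#' Default latent-factor loadings for the cohort generator
#'
#' The generator induces realistic cross-component correlation through four
#' independent standard-normal latent factors per subject:
#' \describe{
#'   \item{severity}{a single metabolic-severity factor loading on all
#'     cardiometabolic components, negatively on HDL-C.  This is what makes
#'     abnormal components cluster within subjects, so that a realistic
#'     fraction of children carries three or more components at once.}
#'   \item{bp}{a blood-pressure factor shared by SBP and DBP, reproducing
#'     the strong SBP-DBP correlation seen in practice (about 0.6).}
#'   \item{size}{a body-size factor shared by weight, height and waist.}
#'   \item{lipid}{a factor shared by total and LDL cholesterol.}
#' }
#' Entries are correlations between the measurement (after removal of the
#' within-band age trend) and the factor; for every measurement the squared
#' loadings sum to less than 1, the remainder being independent Gaussian
#' noise, so configured stratum SDs are reproduced exactly.
#'
#' @return A 10 x 4 numeric matrix, rows named by measurement, columns
#'   `severity`, `bp`, `size`, `lipid`.
#' @seealso [simulate_cohort()]
#' @export
default_loadings <- function() {
  m <- matrix(0, nrow = 10, ncol = 4,
              dimnames = list(cohort_measures(),
                              c("severity", "bp", "size", "lipid")))
  m[, "severity"] <- c(weight = 0.16, height = 0.02, waist = 0.18,
                       sbp = 0.14, dbp = 0.12, fbg = 0.10, tg = 0.18,
                       tc = 0.06, hdl = -0.16, ldl = 0.06)
  m["sbp", "bp"] <- 0.70
  m["dbp", "bp"] <- 0.70
  m[c("weight", "height", "waist"), "size"] <- c(0.60, 0.55, 0.50)
  m[c("tc", "ldl"), "lipid"] <- c(0.80, 0.80)
  m
}

#' Default within-band age slopes for the cohort generator
#'
#' Change per year of age for each measurement, applied within an age band
#' around the band midpoint so band-level means are preserved.  Defaults are
#' the between-band mean differences of the published strata divided by the
#' four-year band spacing.  Triglycerides carry no age slope (the published
#' band means are nearly flat); the weight slope is interpreted on the log
#' scale as a relative change per year.
#'
#' @return Named numeric vector, units per year.
#' @export
default_age_slopes <- function() {
  c(weight = 3.75, height = 4.25, waist = 1.89, sbp = 1.41, dbp = 0.83,
    fbg = 0, tg = 0, tc = -0.27, hdl = -0.21, ldl = -0.13)
}

# Physiologic floors used by the rejection sampler (values must exceed them).
cohort_floors <- function() {
  c(weight = 5, height = 50, waist = 20, sbp = 40, dbp = 20,
    fbg = 30, tg = 10, tc = 50, hdl = 10, ldl = 10)
}

#' Simulate a pediatric cohort with clustered cardiometabolic risk
#'
#' Generates a subject-level table of 7-18-year-olds whose per-stratum means
#' and SDs match the supplied reference (by default the published national
#' survey strata of [reference_strata()]) and whose components are positively
#' inter-correlated through a latent severity factor, so that metabolic
#' syndrome prevalence under the percentile-based modified ATP-III criteria
#' falls near the published 5%.
#'
#' Each subject is assigned a sex (default 52.3% boys) and an age band
#' (default band shares 30/43/27%), with age uniform within the band.  Every
#' measurement is stratum mean + age slope x (age - band midpoint) + a
#' latent-factor combination + independent Gaussian noise, scaled so the
#' configured stratum SD is reproduced.  Triglycerides and weight — both
#' right-skewed in growing children — are generated on the log scale
#' (lognormal, moment-matched to the configured natural-scale mean and SD,
#' with the age slope applied on the log scale under an exact mean
#' correction) to mimic their skew and avoid negative draws.  Subjects
#' violating physiologic floors or `sbp > dbp + 5` are redrawn wholesale
#' (rejection, not clipping, so distributions stay smooth).
#'
#' @param n Number of subjects; `n = 0` returns an empty table.
#' @param seed Optional integer seed; a fixed seed makes the cohort
#'   bit-identical across runs.  The caller's RNG state is restored on exit.
#' @param params Stratum reference table in the format of
#'   [reference_strata()].
#' @param loadings Latent factor loading matrix, see [default_loadings()].
#' @param age_slopes Named per-year slopes, see [default_age_slopes()].
#' @param prop_male Proportion of boys.
#' @param band_props Length-3 proportions of the `7-10`, `11-14`, `15-18`
#'   bands; normalised to sum to 1.
#' @return A data.frame with columns `id`, `age`, `sex` and the ten
#'   measurement columns `weight`, `height`, `waist`, `sbp`, `dbp`, `fbg`,
#'   `tg`, `tc`, `hdl`, `ldl`.  The subjects' latent severity draws are
#'   attached as attribute `latent_severity`.
#' @export
#' @examples
#' co <- simulate_cohort(500, seed = 1)
#' summary(co$age)
simulate_cohort <- function(n, seed = NULL, params = reference_strata(),
                            loadings = default_loadings(),
                            age_slopes = default_age_slopes(),
                            prop_male = 0.523,
                            band_props = c(0.30, 0.43, 0.27)) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 || n != floor(n))
    stop("n must be a single non-negative integer")
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
      stop("seed must be a single integer")
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }
  measures <- cohort_measures()
  stopifnot(all(measures %in% rownames(loadings)),
            all(measures %in% names(age_slopes)))
  loadings <- loadings[measures, , drop = FALSE]
  noise_var <- 1 - rowSums(loadings^2)
  if (any(noise_var <= 0))
    stop("squared loadings must sum to < 1 for every measurement")
  if (prop_male <= 0 || prop_male >= 1) stop("prop_male must be in (0,1)")
  band_props <- band_props / sum(band_props)

  empty <- data.frame(id = integer(), age = numeric(), sex = character())
  for (m in measures) empty[[m]] <- numeric()
  if (n == 0) return(empty)

  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(prop_male, 1 - prop_male))
  band <- sample(age_band_levels(), n, replace = TRUE, prob = band_props)
  band_lo <- c("7-10" = 7, "11-14" = 11, "15-18" = 15)
  age <- band_lo[band] + runif(n, 0, 4)
  stratum <- match(paste(sex, band), paste(params$sex, params$age_band))

  draw <- function(idx) draw_measures(idx, age, stratum, params, loadings,
                                      noise_var, age_slopes)
  drawn <- draw(seq_len(n))
  vals <- drawn$vals
  severity <- drawn$severity
  floors <- cohort_floors()
  for (iter in 1:100) {
    bad <- vals[, "sbp"] <= vals[, "dbp"] + 5
    for (m in measures) bad <- bad | vals[, m] <= floors[m]
    if (!any(bad)) break
    redrawn <- draw(which(bad))
    vals[bad, ] <- redrawn$vals
    severity[bad] <- redrawn$severity
    if (iter == 100) stop("rejection sampling failed to converge")
  }
  out <- data.frame(id = seq_len(n), age = unname(age), sex = sex,
                    stringsAsFactors = FALSE)
  for (m in measures) out[[m]] <- unname(vals[, m])
  # the latent severity draw is kept as an attribute so simulation studies
  # can condition on it; it is not a column of the subject schema
  attr(out, "latent_severity") <- unname(severity)
  out
}

# Draw raw measurement values for the subjects in `idx`.
draw_measures <- function(idx, age, stratum, params, loadings, noise_var,
                          age_slopes) {
  k <- length(idx)
  measures <- rownames(loadings)
  fac <- matrix(stats::rnorm(k * ncol(loadings)), nrow = k,
                dimnames = list(NULL, colnames(loadings)))
  vals <- matrix(NA_real_, nrow = k, ncol = length(measures),
                 dimnames = list(NULL, measures))
  st <- stratum[idx]
  dev_age <- age[idx] - age_band_midpoint(params$age_band[st])
  for (m in measures) {
    mu <- params[[paste0(m, "_mean")]][st]
    sd <- params[[paste0(m, "_sd")]][st]
    z <- fac %*% loadings[m, ] + sqrt(noise_var[m]) * stats::rnorm(k)
    if (m %in% c("tg", "weight")) {
      # right-skewed measures: lognormal, moment-matched on the natural
      # scale so configured stratum means/SDs are reproduced exactly,
      # including the age-slope contribution (slope applied on log scale)
      b <- age_slopes[m] / mu
      A <- ifelse(b == 0, 1, sinh(2 * b) / (2 * b))
      B <- ifelse(b == 0, 1, sinh(4 * b) / (4 * b))
      s2 <- log((1 + (sd / mu)^2) * A^2 / B)
      if (any(s2 <= 0))
        stop("age slope for ", m, " is too steep for the configured SD")
      vals[, m] <- exp(log(mu) - log(A) - s2 / 2 + b * dev_age +
                         sqrt(s2) * z)
    } else {
      resid_var <- sd^2 - age_slopes[m]^2 * (16 / 12)  # Var of U(-2,2)
      if (any(resid_var <= 0))
        stop("age slope for ", m, " is too steep for the configured SD")
      vals[, m] <- mu + age_slopes[m] * dev_age + sqrt(resid_var) * z
    }
  }
  list(vals = vals, severity = fac[, "severity"])
}

#' Per-stratum summary of a cohort
#'
#' Mean, SD and n of every measurement (and derived measure, if present) for
#' each sex-by-age-band stratum, each sex overall, each band overall, and the
#' whole cohort, mirroring the layout of published descriptive tables.
#'
#' @param cohort A subject-level data.frame (see [simulate_cohort()]).
#' @return A long data.frame with columns `age_band`, `sex` (including
#'   `"all"`), `variable`, `n`, `mean`, `sd`.  SD is `NA` for single-subject
#'   cells.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- check_cohort(cohort)
  if (nrow(cohort) == 0) stop("cohort is empty")
  vars <- intersect(c(cohort_measures(), "map", "bmi", "whtr"), names(cohort))
  band <- as.character(age_band(cohort$age))
  groups <- expand.grid(age_band = c(age_band_levels(), "7-18"),
                        sex = c("male", "female", "all"),
                        stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- (groups$age_band[g] == "7-18" | band == groups$age_band[g]) &
      (groups$sex[g] == "all" | cohort$sex == groups$sex[g])
    do.call(rbind, lapply(vars, function(v) {
      x <- cohort[[v]][sel]
      data.frame(age_band = groups$age_band[g], sex = groups$sex[g],
                 variable = v, n = sum(!is.na(x)),
                 mean = if (length(x)) mean(x, na.rm = TRUE) else NA_real_,
                 sd = if (length(x) > 1) stats::sd(x, na.rm = TRUE)
                      else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Read or write a cohort CSV
#'
#' Cohorts are stored as plain CSV, one row per subject, with the column
#' schema of [simulate_cohort()] (header `id, age, sex, weight, height,
#' waist, sbp, dbp, fbg, tg, tc, hdl, ldl`; derived and flag columns may
#' follow).
#'
#' @param cohort A cohort data.frame.
#' @param path File path.
#' @return `read_cohort` returns the validated data.frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  check_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}
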