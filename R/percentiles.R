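#' Empirical within-cohort percentile reference
#'
#' Builds the age/sex/height-adjusted percentile thresholds needed by the
#' percentile-based MetS component rules (90th percentile of SBP and DBP for
#' sex, age and height; 90th percentile of waist for sex and age; 85th and
#' 95th BMI percentiles for sex and age) directly from the analysis cohort,
#' substituting for external normative tables.
#'
#' Subjects are binned by sex and integer age-year; bins with fewer than
#' `min_bin` subjects are merged with the adjacent age until all bins are
#' large enough.  Within each sex-by-age bin, height adjustment uses height
#' tertiles, and blood-pressure percentiles are computed within each
#' sex-by-age-by-tertile cell.  All percentiles use the linear-interpolation
#' estimator (Hyndman-Fan type 7, the [stats::quantile()] default).
#'
#' @param cohort Subject-level data.frame; BMI is derived if absent.
#' @param level Percentile level for the BP and waist rules (default 90).
#' @param min_bin Minimum subjects per sex-by-age bin before merging.
#' @return An object of class `percentile_reference` with `mode =
#'   "empirical"`, usable by [classify_mets()] and [lookup_reference()].
#' @export
empirical_reference <- function(cohort, level = 90, min_bin = 20) {
  stopifnot(level > 0, level <= 100, min_bin >= 1)
  cohort <- add_derived(check_cohort(cohort))
  sexes <- c("male", "female")
  tables <- lapply(sexes, function(s) {
    sub <- cohort[cohort$sex == s & !is.na(cohort$age), ]
    if (nrow(sub) < min_bin)
      stop("too few ", s, " subjects to form percentile bins")
    ageyr <- pmin(floor(sub$age), 18L)
    grp <- merge_age_bins(ageyr, min_bin)
    groups <- lapply(split(seq_len(nrow(sub)), grp$group[match(ageyr,
                                                               grp$age)]),
                     function(idx) {
      d <- sub[idx, ]
      hbr <- stats::quantile(d$height, c(1, 2) / 3, type = 7, names = FALSE,
                             na.rm = TRUE)
      tert <- 1L + (d$height > hbr[1]) + (d$height > hbr[2])
      bp <- t(vapply(1:3, function(tt) {
        dt <- d[tert == tt, ]
        if (nrow(dt) == 0) return(c(NA_real_, NA_real_))
        c(stats::quantile(dt$sbp, level / 100, type = 7, names = FALSE,
                          na.rm = TRUE),
          stats::quantile(dt$dbp, level / 100, type = 7, names = FALSE,
                          na.rm = TRUE))
      }, numeric(2)))
      colnames(bp) <- c("sbp", "dbp")
      list(
        wc_p = stats::quantile(d$waist, level / 100, type = 7, names = FALSE,
                               na.rm = TRUE),
        bmi_p85 = stats::quantile(d$bmi, 0.85, type = 7, names = FALSE,
                                  na.rm = TRUE),
        bmi_p95 = stats::quantile(d$bmi, 0.95, type = 7, names = FALSE,
                                  na.rm = TRUE),
        height_breaks = hbr,
        bp = bp
      )
    })
    list(age_map = grp, groups = groups)
  })
  names(tables) <- sexes
  structure(list(mode = "empirical", level = level, min_bin = min_bin,
                 tables = tables),
            class = "percentile_reference")
}

# Merge integer age-years into contiguous groups of size >= min_bin.
# Returns data.frame(age, group) mapping each observed age-year to a group id.
merge_age_bins <- function(ageyr, min_bin) {
  tab <- table(ageyr)
  ages <- as.integer(names(tab))
  counts <- as.integer(tab)
  group <- seq_along(ages)
  repeat {
    sizes <- tapply(counts, group, sum)
    small <- names(sizes)[sizes < min_bin]
    if (length(small) == 0) break
    gids <- sort(unique(group))
    if (length(gids) == 1)
      stop("age bins too small even after merging")
    g <- as.integer(small[1])
    pos <- match(g, gids)
    neighbors <- c(if (pos > 1) gids[pos - 1], if (pos < length(gids))
      gids[pos + 1])
    target <- neighbors[which.min(sizes[as.character(neighbors)])]
    group[group == g] <- target
  }
  data.frame(age = ages, group = match(group, sort(unique(group))))
}

#' @export
print.percentile_reference <- function(x, ...) {
  cat("Percentile reference (mode:", x$mode, ", level:", x$level, ")\n")
  for (s in names(x$tables))
    cat(" ", s, ":", length(x$tables[[s]]$groups), "age groups\n")
  invisible(x)
}

#' Load an external blood-pressure percentile reference
#'
#' Reads a normative-table CSV with columns `sex`, `age_year`,
#' `height_percentile_band` (height tertile 1-3 within sex and age),
#' `sbp_p90`, `dbp_p90` and combines it with within-cohort height tertile
#' breaks and waist/BMI percentiles (which external BP tables do not carry).
#' The table must cover every sex-by-age-year cell present in the cohort.
#'
#' @param path Path to the reference CSV.
#' @param cohort Cohort data.frame used for height tertile breaks and
#'   waist/BMI percentiles.
#' @param level Percentile level of the waist rule (default 90).
#' @param min_bin Minimum subjects per bin (see [empirical_reference()]).
#' @return A `percentile_reference` with `mode = "external"`.
#' @export
external_reference <- function(path, cohort, level = 90, min_bin = 20) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sex", "age_year", "height_percentile_band", "sbp_p90",
              "dbp_p90")
  if (!all(needed %in% names(tab)))
    stop("external reference must have columns: ",
         paste(needed, collapse = ", "))
  if (any(tab$sbp_p90 <= tab$dbp_p90))
    stop("external reference requires sbp_p90 > dbp_p90")
  ref <- empirical_reference(cohort, level = level, min_bin = min_bin)
  cohort <- check_cohort(cohort)
  cells <- unique(data.frame(sex = cohort$sex,
                             age_year = pmin(floor(cohort$age), 18L)))
  have <- unique(tab[, c("sex", "age_year")])
  miss <- !paste(cells$sex, cells$age_year) %in% paste(have$sex,
                                                       have$age_year)
  if (any(miss))
    stop("external reference does not cover cells: ",
         paste(paste(cells$sex[miss], cells$age_year[miss]), collapse = "; "))
  ref$mode <- "external"
  ref$bp_table <- tab
  ref
}

#' Look up percentile thresholds for subjects
#'
#' Resolves, for each subject, the 90th-percentile SBP/DBP for their sex,
#' age and height tertile, the waist percentile for their sex and age, and
#' the 85th/95th BMI percentiles.
#'
#' @param ref A `percentile_reference` from [empirical_reference()] or
#'   [external_reference()].
#' @param sex,age,height Subject vectors (same length).
#' @return data.frame with columns `sbp_p`, `dbp_p`, `wc_p`, `bmi_p85`,
#'   `bmi_p95`.
#' @export
lookup_reference <- function(ref, sex, age, height) {
  stopifnot(inherits(ref, "percentile_reference"))
  n <- length(sex)
  out <- data.frame(sbp_p = rep(NA_real_, n), dbp_p = NA_real_,
                    wc_p = NA_real_, bmi_p85 = NA_real_, bmi_p95 = NA_real_)
  ageyr <- pmin(floor(age), 18L)
  for (s in c("male", "female")) {
    st <- ref$tables[[s]]
    sel <- which(sex == s & !is.na(age))
    if (!length(sel)) next
    gid <- st$age_map$group[match(ageyr[sel], st$age_map$age)]
    for (g in unique(gid[!is.na(gid)])) {
      rows <- sel[which(gid == g)]
      grp <- st$groups[[as.character(g)]]
      out$wc_p[rows] <- grp$wc_p
      out$bmi_p85[rows] <- grp$bmi_p85
      out$bmi_p95[rows] <- grp$bmi_p95
      tert <- 1L + (height[rows] > grp$height_breaks[1]) +
        (height[rows] > grp$height_breaks[2])
      if (ref$mode == "empirical") {
        out$sbp_p[rows] <- grp$bp[tert, "sbp"]
        out$dbp_p[rows] <- grp$bp[tert, "dbp"]
      } else {
        key <- paste(s, ageyr[rows], tert)
        tkey <- paste(ref$bp_table$sex, ref$bp_table$age_year,
                      ref$bp_table$height_percentile_band)
        hit <- match(key, tkey)
        out$sbp_p[rows] <- ref$bp_table$sbp_p90[hit]
        out$dbp_p[rows] <- ref$bp_table$dbp_p90[hit]
      }
    }
  }
  out
}
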