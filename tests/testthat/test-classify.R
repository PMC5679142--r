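# helper: a minimal hand-built cohort row
subject_row <- function(id, sex, age, tg = 80, hdl = 50, fbg = 90,
                        waist = 48, height = 120, sbp = 100, dbp = 70,
                        weight = 30, tc = 150, ldl = 90) {
  data.frame(id = id, age = age, sex = sex, weight = weight,
             height = height, waist = waist, sbp = sbp, dbp = dbp,
             fbg = fbg, tg = tg, tc = tc, hdl = hdl, ldl = ldl,
             stringsAsFactors = FALSE)
}

test_that("criteria presets carry the documented thresholds and comparators", {
  mt <- mets_criteria("methods_text")
  expect_equal(mt$tg, list(op = ">=", value = 150))
  expect_equal(mt$hdl$op, "<=")
  expect_equal(mt$hdl$value, 40)
  expect_null(mt$hdl$male_15_18)
  expect_equal(mt$fbg, list(op = ">=", value = 100))
  expect_equal(mt$abdominal, "whtr_gt_0.5")
  tf <- mets_criteria("table_footnote")
  expect_equal(tf$tg, list(op = ">", value = 100))
  expect_equal(tf$hdl$op, "<")
  expect_equal(tf$hdl$male_15_18, 45)  # boys 15-18 use the higher cutoff
  expect_equal(tf$abdominal, "wc_gt_pct")
  expect_error(mets_criteria("unknown"))
  expect_output(print(tf), "45 mg/dL")
})

test_that("criteria round-trip through YAML", {
  cr <- mets_criteria("table_footnote")
  cr$tg$value <- 120
  path <- withr::local_tempfile(fileext = ".yaml")
  write_criteria(cr, path)
  back <- read_criteria(path)
  expect_equal(back$tg$value, 120)
  expect_equal(back$hdl$male_15_18, 45)
  expect_s3_class(back, "mets_criteria")
})

test_that("empirical percentiles use the linear-interpolation estimator", {
  co <- rbind(
    do.call(rbind, lapply(1:100, function(k)
      subject_row(k, "male", 9.5, sbp = 100 + k, dbp = 50, waist = k))),
    do.call(rbind, lapply(1:100, function(k)
      subject_row(100 + k, "female", 9.5, waist = 5))))
  ref <- empirical_reference(co, level = 90)
  lk <- lookup_reference(ref, co$sex, co$age, co$height)
  # type-7 percentile of a 100-point grid at level 90 falls at rank 90.1
  expect_equal(lk$sbp_p[co$sex == "male"][1], 100 + 90.1)
  expect_equal(lk$wc_p[co$sex == "male"][1], 90.1)
  # constant bin: percentile equals the constant
  expect_equal(lk$wc_p[co$sex == "female"][1], 5)
  # level 100 returns the maximum
  ref100 <- empirical_reference(co, level = 100)
  lk100 <- lookup_reference(ref100, co$sex, co$age, co$height)
  expect_equal(lk100$wc_p[co$sex == "male"][1], 100)
})

test_that("undersized age bins merge with the adjacent year", {
  co <- rbind(
    do.call(rbind, lapply(1:30, function(k) subject_row(k, "male", 9.5))),
    do.call(rbind, lapply(1:5, function(k)
      subject_row(30 + k, "male", 10.5))),
    do.call(rbind, lapply(1:30, function(k)
      subject_row(40 + k, "female", 9.5))))
  ref <- empirical_reference(co, min_bin = 20)
  am <- ref$tables$male$age_map
  expect_equal(am$group[am$age == 9], am$group[am$age == 10])
  tiny <- co[co$id <= 10, ]
  expect_error(empirical_reference(tiny, min_bin = 20), "too few")
})

test_that("component comparators are strict or inclusive exactly as configured", {
  ages <- c(9, 14, 16)
  bp_ref <- write_flat_bp_reference(withr::local_tempfile(fileext = ".csv"),
                                    ages)
  co <- rbind(subject_row(1, "male", 9.5, tg = 150),
              subject_row(2, "male", 9.5, tg = 149.99),
              subject_row(3, "male", 9.5, tg = 100),
              subject_row(4, "male", 9.5, tg = 100.01),
              subject_row(5, "male", 16.5, hdl = 42),
              subject_row(6, "female", 16.5, hdl = 42),
              subject_row(7, "male", 14.5, hdl = 42),
              subject_row(8, "male", 9.5, hdl = 40),
              subject_row(9, "male", 9.5, fbg = 100),
              subject_row(10, "female", 9.5, fbg = 100))
  ref <- external_reference(bp_ref, co, min_bin = 1)
  mt <- suppressMessages(classify_mets(co, mets_criteria("methods_text"),
                                       ref))
  tf <- suppressMessages(classify_mets(co, mets_criteria("table_footnote"),
                                       ref))
  expect_true(mt$high_tg[1])     # TG >= 150 inclusive
  expect_false(mt$high_tg[2])
  expect_false(mt$high_tg[3])    # 100 not high under the 150 rule
  expect_true(tf$high_tg[1])
  expect_false(tf$high_tg[3])    # strict > 100
  expect_true(tf$high_tg[4])
  expect_true(mt$low_hdl[8])     # HDL <= 40 inclusive
  expect_false(tf$low_hdl[8])    # HDL < 40 strict
  expect_true(tf$low_hdl[5])     # boy 15-18: cutoff 45
  expect_false(tf$low_hdl[6])    # girl keeps 40
  expect_false(tf$low_hdl[7])    # boy 11-14 keeps 40
  expect_true(mt$high_fbg[9])    # FBG >= 100 inclusive
  expect_false(tf$high_fbg[10])  # FBG > 100 strict
})

test_that("MetS flag equals brute-force counting over all 32 flag combinations", {
  combos <- expand.grid(tg = c(0, 1), hdl = c(0, 1), fbg = c(0, 1),
                        abd = c(0, 1), bp = c(0, 1))
  co <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    subject_row(i, if (i %% 2) "male" else "female", 9.5,
                tg = if (cb$tg) 160 else 100,
                hdl = if (cb$hdl) 35 else 50,
                fbg = if (cb$fbg) 110 else 90,
                waist = if (cb$abd) 72 else 48,   # whtr 0.6 vs 0.4
                sbp = if (cb$bp) 120 else 100)    # external p90 = 110
  }))
  bp_ref <- write_flat_bp_reference(withr::local_tempfile(fileext = ".csv"),
                                    9)
  ref <- external_reference(bp_ref, co, min_bin = 1)
  cl <- suppressMessages(classify_mets(co, mets_criteria("methods_text"),
                                       ref))
  expected_n <- rowSums(combos)
  expect_equal(cl$n_components, as.integer(expected_n))
  expect_equal(cl$mets, expected_n >= 3)
  expect_equal(cl$high_tg, combos$tg == 1)
  expect_equal(cl$elevated_bp, combos$bp == 1)
  expect_equal(cl$abdominal_obesity, combos$abd == 1)
})

test_that("raising a threshold never increases the flagged count", {
  co <- cached_cohort(5000, 2)
  base <- mets_criteria("table_footnote")
  higher <- base
  higher$tg$value <- 140
  ref <- empirical_reference(co)
  a <- suppressMessages(classify_mets(co, base, ref))
  b <- suppressMessages(classify_mets(co, higher, ref))
  expect_lte(sum(b$high_tg), sum(a$high_tg))
  expect_lte(sum(b$n_components), sum(a$n_components))
  expect_lte(sum(b$mets), sum(a$mets))
})

test_that("per-bin flagged fractions respect the percentile level", {
  co <- cached_cohort(5000, 2)
  ref <- empirical_reference(co, level = 90)
  cl <- suppressMessages(classify_mets(co, mets_criteria("table_footnote"),
                                       ref))
  for (s in c("male", "female")) {
    st <- ref$tables[[s]]
    ageyr <- pmin(floor(co$age), 18)
    for (g in unique(st$age_map$group)) {
      in_grp <- co$sex == s &
        st$age_map$group[match(ageyr, st$age_map$age)] %in% g
      grp <- st$groups[[as.character(g)]]
      tert <- 1 + (co$height > grp$height_breaks[1]) +
        (co$height > grp$height_breaks[2])
      for (tt in 1:3) {
        sel <- which(in_grp & tert == tt)
        if (length(sel) == 0) next
        frac <- mean(cl$elevated_sbp[sel])
        expect_lte(frac, 0.10 + 1 / length(sel))
      }
      sel_g <- which(in_grp)
      expect_lte(mean(cl$abdominal_obesity[sel_g]),
                 0.10 + 1 / length(sel_g))
    }
  }
})

test_that("secondary flags follow the strict LDL/TC cutoffs and BMI percentiles", {
  co <- rbind(
    do.call(rbind, lapply(1:100, function(k)
      subject_row(k, "male", 9.5, weight = k, height = 100))),   # bmi = k
    do.call(rbind, lapply(1:100, function(k)
      subject_row(100 + k, "female", 9.5, weight = k, height = 100))))
  co$ldl[1:4] <- c(110, 110.1, 90, 120)
  co$tc[1:3] <- c(200, 200.1, 150)
  sf <- secondary_flags(co)
  expect_false(sf$high_ldl[1])   # strict > 110
  expect_true(sf$high_ldl[2])
  expect_true(sf$high_ldl[4])
  expect_false(sf$high_tc[1])    # strict > 200
  expect_true(sf$high_tc[2])
  # bmi values 1..100: p85 = 85.15, p95 = 95.05 (type 7)
  males <- sf[sf$sex == "male", ]
  expect_equal(males$weight[males$obese], 96:100)
  expect_equal(males$weight[males$overweight], 86:95)
  expect_false(any(sf$overweight & sf$obese))
})

test_that("missing measurements leave subjects unevaluable but retained", {
  co <- cached_cohort(200, 4)
  co$tg[5] <- NA
  expect_message(cl <- classify_mets(co, mets_criteria("table_footnote")),
                 "unevaluable")
  expect_true(is.na(cl$n_components[5]))
  expect_true(is.na(cl$mets[5]))
  expect_equal(attr(cl, "exclusions"), 1)
  expect_equal(nrow(cl), 200)
})
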