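test_that("ATPIII agrees with brute-force enumeration of all 32 flag combinations", {
  for (sex in c("male", "female")) {
    cc <- combo_cohort(sex)
    comp <- atpiii_components(cc$cohort)
    expect_equal(comp$atpiii_count, cc$n_flags)
    expect_equal(classify_atpiii(cc$cohort), cc$n_flags >= 3)
  }
})

test_that("IDF requires central obesity plus any two secondary components", {
  for (waist_on in c(TRUE, FALSE)) {
    fv <- flag_values("male")
    grid <- expand.grid(tg = 0:1, hdl = 0:1, bp = 0:1, fpg = 0:1)
    recs <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      make_record(waist = if (waist_on) 95 else 89,
                  tg = fv$tg[[2 - g$tg]], hdl = fv$hdl[[2 - g$hdl]],
                  sbp = fv$sbp[[2 - g$bp]], dbp = 70,
                  fpg = fv$fpg[[2 - g$fpg]])
    })
    cohort <- do.call(make_cohort, recs)
    expected <- waist_on & rowSums(grid) >= 2
    expect_equal(classify_idf(cohort), expected)
  }
})

test_that("every rule threshold is honoured on both sides of the boundary", {
  ## ATPIII waist: >= 102 (men), >= 88 (women); IDF waist: > 90 strictly
  expect_equal(atpiii_components(make_cohort(
    make_record(waist = 102), make_record(waist = 101.9),
    make_record(sex = "female", waist = 88),
    make_record(sex = "female", waist = 87.9)))$abdominal_obesity_atpiii,
    c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(classify_idf(make_cohort(
    make_record(waist = 90, tg = 160, hdl = 35),
    make_record(waist = 90.1, tg = 160, hdl = 35))), c(FALSE, TRUE))
  ## tg >= 150, fpg >= 100, sbp >= 130, dbp >= 85
  comp <- atpiii_components(make_cohort(
    make_record(tg = 150), make_record(tg = 149.9),
    make_record(fpg = 100), make_record(fpg = 99.9),
    make_record(sbp = 130), make_record(sbp = 129.9),
    make_record(dbp = 85), make_record(dbp = 84.9)))
  expect_equal(comp$high_tg[1:2], c(TRUE, FALSE))
  expect_equal(comp$high_fpg[3:4], c(TRUE, FALSE))
  expect_equal(comp$high_bp[5:8], c(TRUE, FALSE, TRUE, FALSE))
  ## HDL < 40 (men) / < 50 (women)
  expect_equal(atpiii_components(make_cohort(
    make_record(hdl = 40), make_record(hdl = 39.9),
    make_record(sex = "female", hdl = 50),
    make_record(sex = "female", hdl = 49.9)))$low_hdl,
    c(FALSE, TRUE, FALSE, TRUE))
  ## normal subject: tc <= 200 and bmi <= 25 inclusive
  nrm <- derive_clinical(make_cohort(
    make_record(tc = 200), make_record(tc = 200.1),
    make_record(weight = 25 * 1.75^2),            # bmi exactly 25
    make_record(weight = 25.1 * 1.75^2)))
  expect_equal(is_metabolically_normal(nrm), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("medication satisfies the blood-pressure component and breaks normality", {
  rec <- make_record(sbp = 120, dbp = 70, antihypertensive_med = TRUE)
  expect_true(atpiii_components(rec)$high_bp)
  expect_false(is_metabolically_normal(derive_clinical(rec)))
  ## boundary example: tg and fpg inclusive + medication rule -> count 3
  woman <- make_record(sex = "female", waist = 80, tg = 150, hdl = 50,
                       sbp = 128, dbp = 80, antihypertensive_med = TRUE,
                       fpg = 100)
  expect_equal(atpiii_components(woman)$atpiii_count, 3L)
})

test_that("diabetes stratum follows the selected rule", {
  cohort <- make_cohort(
    make_record(diabetes_history = TRUE, fpg = 90),
    make_record(diabetes_history = FALSE, fpg = 130),
    make_record(diabetes_history = FALSE, fpg = 100),
    make_record(diabetes_history = FALSE, fpg = 126))
  expect_equal(diabetes_stratum(cohort, "history_or_fpg126"),
               c("diabetic", "diabetic", "nondiabetic", "diabetic"))
  expect_equal(diabetes_stratum(cohort, "history_only"),
               c("diabetic", "nondiabetic", "nondiabetic", "nondiabetic"))
  ## diabetes satisfies the glucose component even at normal fpg
  expect_true(atpiii_components(cohort[1, ])$high_fpg)
})

test_that("worsening any single component never clears a MetS label", {
  worse <- list(waist = 15, tg = 80, hdl = -12, sbp = 25, dbp = 12,
                fpg = 30)
  set.seed(11)
  for (k in 1:40) {
    rec <- make_record(sex = sample(c("male", "female"), 1),
                       waist = runif(1, 70, 110), tg = runif(1, 60, 300),
                       hdl = runif(1, 30, 65), sbp = runif(1, 100, 150),
                       dbp = runif(1, 60, 95), fpg = runif(1, 80, 130))
    for (v in names(worse)) {
      rec2 <- rec
      rec2[[v]] <- rec[[v]] + worse[[v]]
      expect_true(classify_atpiii(rec2) >= classify_atpiii(rec))
      expect_true(classify_idf(rec2) >= classify_idf(rec))
    }
  }
})

test_that("assessment table satisfies its structural invariants", {
  cohort <- derive_clinical(apply_exclusions(generate_cohort(
    survey_config(n = 2000, seed = 5)))$retained)
  m <- assess_mets(cohort)
  expect_equal(m$mets_atpiii, m$atpiii_count >= 3)
  expect_true(all(m$central_obesity_idf[m$mets_idf]))
  expect_false(any(m$mets_idf[cohort$waist <= 90]))
  expect_false(any(m$metabolically_normal & (m$mets_atpiii | m$mets_idf)))
  ## normal subjects carry none of the tg/hdl/bp/fpg components
  nrm <- m$metabolically_normal
  expect_false(any(m$high_tg[nrm] | m$low_hdl[nrm] | m$high_bp[nrm] |
                     m$high_fpg[nrm]))
  expect_error(atpiii_components(make_record(waist = NA_real_)),
               class = "homacut_incomplete_record")
})
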