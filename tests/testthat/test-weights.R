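test_that("post-stratification weights equal hand-computed census/sample ratios", {
  ## 4-stratum fixture with known counts: 2, 4, 6, 8 records
  cohort <- data.frame(
    age = rep(c(30L, 40L, 30L, 40L), times = c(2, 4, 6, 8)),
    sex = rep(c("male", "male", "female", "female"), times = c(2, 4, 6, 8)))
  census <- data.frame(age_band = c("25-34", "35-44", "25-34", "35-44"),
                       sex = c("male", "male", "female", "female"),
                       proportion = c(0.3, 0.3, 0.2, 0.2))
  w <- poststratification_weights(cohort, census)
  raw <- c(0.3 / (2 / 20), 0.3 / (4 / 20), 0.2 / (6 / 20), 0.2 / (8 / 20))
  expected <- rep(raw, times = c(2, 4, 6, 8))
  expect_equal(as.numeric(w), expected / mean(expected), tolerance = 1e-12)
  ## identity case: sample shares equal to census -> all weights 1
  census_eq <- census
  census_eq$proportion <- c(2, 4, 6, 8) / 20
  expect_equal(as.numeric(poststratification_weights(cohort, census_eq)),
               rep(1, 20))
  ## a stratum sampled at half its census share gets twice the weight
  c2 <- data.frame(age_band = c("25-34", "35-44"), sex = "male",
                   proportion = c(0.5, 0.5))
  s2 <- data.frame(age = rep(c(30L, 40L), times = c(5, 15)), sex = "male")
  w2 <- poststratification_weights(s2, c2)
  expect_equal(unname(w2[1] / mean(w2)), 2)
})

test_that("re-aggregating weighted stratum shares reproduces the census", {
  set.seed(21)
  census <- default_census()
  cohort <- generate_cohort(survey_config(n = 5000, seed = 21))
  w <- poststratification_weights(cohort, census)
  key <- attr(w, "stratum")
  shares <- tapply(w, key, sum) / sum(w)
  ckey <- paste(census$age_band, census$sex, sep = ":")
  expect_equal(as.numeric(shares[ckey]), census$proportion,
               tolerance = 1e-12)
})

test_that("census strata missing from the sample are dropped with a warning", {
  cohort <- data.frame(age = c(30L, 30L), sex = "male")
  census <- data.frame(age_band = c("25-34", "35-44"), sex = "male",
                       proportion = c(0.6, 0.4))
  expect_warning(w <- poststratification_weights(cohort, census),
                 class = "homacut_empty_stratum")
  expect_equal(as.numeric(w), c(1, 1))
  bad <- data.frame(age_band = "25-34", sex = "male", proportion = 0.5)
  expect_error(poststratification_weights(cohort, bad),
               class = "homacut_bad_census")
})

test_that("weighted estimators reduce to unweighted counterparts at equal weights", {
  set.seed(31)
  for (k in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    w <- rep(runif(1, 0.5, 2), n)
    ms <- weighted_mean_sem(x, w)
    expect_equal(unname(ms["mean"]), mean(x), tolerance = 1e-12)
    expect_equal(unname(ms["sem"]), sd(x) / sqrt(n), tolerance = 1e-10)
    expect_equal(weighted_percentile(x, w, c(0, 25, 50, 100)),
                 weighted_percentile(x, NULL, c(0, 25, 50, 100)))
    expect_equal(weighted_prevalence(x > 0, w), mean(x > 0))
    expect_equal(weighted_pearson(x, y, w), cor(x, y), tolerance = 1e-12)
  }
})

test_that("hand-computed weighted fixtures are reproduced", {
  expect_equal(unname(weighted_mean_sem(c(1, 2, 3), c(1, 1, 2))["mean"]),
               2.25)
  expect_equal(unname(weighted_mean_sem(c(5, 5, 5), c(1, 2, 3))["sem"]), 0)
  expect_equal(weighted_percentile(c(1, 2, 3), NULL, 50), 2)
  expect_equal(weighted_percentile(c(5, 10), c(2, 1), c(0, 100)), c(5, 10))
  expect_equal(weighted_prevalence(c(TRUE, FALSE, TRUE), c(1, 2, 1)), 0.5)
  expect_equal(weighted_pearson(1:5, 5:1), -1)
  expect_equal(weighted_pearson(1:5, 1:5 * 2 + 3), 1)
})

test_that("integer-weight expansion equivalence holds for mean, percentile, prevalence", {
  set.seed(41)
  for (k in 1:30) {
    n <- sample(3:15, 1)
    x <- round(rnorm(n), 1)
    cnt <- sample(1:4, n, replace = TRUE)
    xe <- rep(x, cnt)
    expect_equal(unname(weighted_mean_sem(x, cnt)["mean"]), mean(xe),
                 tolerance = 1e-12)
    p <- runif(4, 0, 100)
    expect_equal(weighted_percentile(x, cnt, p),
                 weighted_percentile(xe, NULL, p), tolerance = 1e-12)
    expect_equal(weighted_prevalence(x > 0, cnt), mean(xe > 0),
                 tolerance = 1e-12)
  }
})

test_that("weighted percentile is monotone in p and guards its arguments", {
  set.seed(51)
  x <- rnorm(200); w <- runif(200, 0.1, 5)
  p <- seq(0, 100, by = 2.5)
  q <- weighted_percentile(x, w, p)
  expect_true(all(diff(q) >= 0))
  expect_equal(q[1], min(x)); expect_equal(q[length(q)], max(x))
  expect_error(weighted_percentile(x, w, 101),
               class = "homacut_invalid_argument")
  expect_error(weighted_mean_sem(1), class = "homacut_insufficient_data")
  expect_error(weighted_pearson(rep(1, 5), 1:5),
               class = "homacut_degenerate_input")
})
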