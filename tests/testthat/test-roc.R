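test_that("the empirical ROC satisfies its monotonicity and endpoint invariants", {
  set.seed(61)
  for (k in 1:20) {
    f <- random_roc_fixture()
    r <- wroc(f$score, f$label, f$w)
    expect_true(all(diff(r$sensitivity) <= 1e-12))
    expect_true(all(diff(r$specificity) >= -1e-12))
    expect_equal(r$sensitivity[1], 1); expect_equal(r$specificity[1], 0)
    k <- length(r$thresholds)
    expect_equal(r$sensitivity[k], 0); expect_equal(r$specificity[k], 1)
    expect_true(all(diff(r$thresholds) > 0))
  }
})

test_that("separated classes give a threshold with perfect performance", {
  r <- wroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  i <- which(r$thresholds == 2.5)
  expect_equal(r$sensitivity[i], 1)
  expect_equal(r$specificity[i], 1)
  expect_equal(auc(r), 1)
})

test_that("fully tied scores collapse the curve to the chance corners", {
  r <- wroc(rep(2, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(length(r$thresholds), 2L)
  expect_equal(auc(r), 0.5)
  expect_error(optimal_cutpoint(r), class = "homacut_no_cutpoint")
  expect_error(wroc(1:4, rep(TRUE, 4)), class = "homacut_degenerate_labels")
})

test_that("trapezoidal AUC matches an established ROC implementation on unweighted data", {
  skip_if_not_installed("pROC")
  set.seed(71)
  for (k in 1:10) {
    f <- random_roc_fixture()
    ours <- auc(f$score, f$label)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = f$label, predictor = f$score, levels = c(FALSE, TRUE),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant to increasing score transforms and flips under label swap", {
  set.seed(81)
  for (k in 1:20) {
    f <- random_roc_fixture()
    a <- auc(f$score, f$label, f$w)
    expect_equal(auc(exp(f$score / 3), f$label, f$w), a, tolerance = 1e-12)
    expect_equal(auc(f$score, !f$label, f$w), 1 - a, tolerance = 1e-12)
    ## selected operating point is transform-invariant too
    r1 <- optimal_cutpoint(wroc(f$score, f$label, f$w), "youden")
    r2 <- optimal_cutpoint(wroc(exp(f$score / 3), f$label, f$w), "youden")
    expect_equal(r1$sensitivity, r2$sensitivity, tolerance = 1e-12)
    expect_equal(r1$specificity, r2$specificity, tolerance = 1e-12)
  }
})

test_that("criterion plateaus break ties at the lowest threshold and report the interval", {
  ## symmetric two-corner fixture: thresholds 1.5 and 2.5 tie exactly
  score <- c(1, 1, 2, 2, 3, 3)
  label <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- wroc(score, label)
  cp <- optimal_cutpoint(r, "youden")
  expect_equal(cp$threshold, 1.5)
  expect_equal(cp$n_tied, 2L)
  expect_equal(unname(cp$plateau), c(1.5, 2.5))
  ## youden and distance agree on a symmetric curve
  cpd <- optimal_cutpoint(r, "distance")
  expect_equal(cpd$threshold, cp$threshold)
  ## consistency of the derived statistics
  expect_equal(cp$youden_j, cp$sensitivity + cp$specificity - 1)
  expect_equal(cp$youden_paper_scale, cp$youden_j + 1)
  expect_equal(cp$distance_sq,
               (1 - cp$sensitivity)^2 + (1 - cp$specificity)^2)
})

test_that("percentile tables equal brute-force recomputation on a small cohort", {
  set.seed(91)
  n <- 20
  score <- round(rlnorm(n, 0.5, 0.5), 2)
  label <- runif(n) < plogis(score - 1.5)
  if (!any(label)) label[which.max(score)] <- TRUE
  if (all(label)) label[which.min(score)] <- FALSE
  w <- runif(n, 0.5, 2)
  tab <- percentile_table(score, label, w)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$percentile, seq(50, 95, by = 5))
  expect_true(all(diff(tab$sensitivity) <= 1e-12))
  P <- sum(w[label]); N <- sum(w[!label])
  for (i in seq_len(nrow(tab))) {
    t <- tab$threshold[i]
    se <- sum(w[label & score >= t]) / P
    sp <- sum(w[!label & score < t]) / N
    expect_equal(tab$sensitivity[i], se, tolerance = 1e-12)
    expect_equal(tab$specificity[i], sp, tolerance = 1e-12)
    expect_equal(tab$plr[i], if (sp == 1) Inf else se / (1 - sp),
                 tolerance = 1e-12)
  }
})

test_that("the bootstrap interval is seeded, reproducible, and brackets the estimate", {
  set.seed(101)
  f <- random_roc_fixture(40)
  ci1 <- auc_bootstrap_ci(f$score, f$label, f$w, B = 200, seed = 7)
  ci2 <- auc_bootstrap_ci(f$score, f$label, f$w, B = 200, seed = 7)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  pt <- attr(ci1, "point")
  expect_equal(pt, auc(f$score, f$label, f$w))
  expect_true(ci1[1] <= pt && pt <= ci1[2])
  expect_error(auc_bootstrap_ci(f$score, f$label, B = 50),
               class = "homacut_invalid_argument")
})
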