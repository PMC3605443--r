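test_that("AUC handles separation, ties, and matches pair counting", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(3, 8), c(0, 1, 0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(13)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    scores <- sample(1:6, n, replace = TRUE)  # force ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(21)
  scores <- rnorm(40); labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  base <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), base)
  expect_equal(roc_auc(qnorm(pnorm(scores))^3 + scores^5 + 10 * scores, labels),
               base)
})

test_that("optimal cutoff matches exhaustive enumeration", {
  oc <- optimal_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(oc$cutoff, 2.5)
  expect_equal(oc$sensitivity, 1)
  expect_equal(oc$specificity, 1)

  set.seed(31)
  for (i in 1:30) {
    n <- sample(6:15, 1)
    scores <- round(runif(n, 0, 1), 2)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    got <- optimal_cutoff(scores, labels)
    want <- brute_cutoff(scores, labels)
    expect_equal(got$sensitivity + got$specificity, want$youden)
    expect_equal(got$cutoff, want$cutoff)  # lowest qualifying cutoff
  }
})

test_that("exact binomial intervals match closed forms", {
  expect_equal(proportion_ci(30, 30)[["lower"]], 100 * 0.025^(1 / 30),
               tolerance = 1e-9)
  expect_equal(proportion_ci(30, 30)[["upper"]], 100)
  ci0 <- proportion_ci(0, 20)
  expect_equal(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], 100 * (1 - 0.025^(1 / 20)), tolerance = 1e-9)
  expect_error(proportion_ci(5, 0), "`n`")
  # published Table-2-style row: sensitivity 30/33 = 90.91% (CI 75.67-98.08),
  # specificity 25/26 = 96.15% (CI 80.36-99.90)
  expect_equal(unname(proportion_ci(30, 33)), c(75.67, 98.08), tolerance = 0.005)
  expect_equal(unname(proportion_ci(25, 26)), c(80.36, 99.90), tolerance = 0.005)
})

test_that("log Bland-Altman reduces to zero width for identical pairs", {
  x <- c(0.01, 0.05, 0.2, 0.4)
  ba <- bland_altman_log(x, x)
  expect_equal(ba$mean_diff_log, 0)
  expect_equal(ba$sd_diff_log, 0)
  expect_equal(c(ba$ratio_low, ba$ratio_high), c(1, 1))
  expect_error(bland_altman_log(c(1, 2, 0), c(1, 2, 3)), "pair\\(s\\): 3")
})

test_that("limits are symmetric and ratio bounds multiply to exp(2 mean)", {
  set.seed(8)
  x <- exp(rnorm(40, -3, 0.8)); y <- x * exp(rnorm(40, 0.1, 0.4))
  ba <- bland_altman_log(x, y)
  expect_equal(ba$loa_high - ba$mean_diff_log, ba$mean_diff_log - ba$loa_low)
  expect_equal(ba$ratio_low * ba$ratio_high, exp(2 * ba$mean_diff_log))
  expect_lt(ba$loa_low_ci[1], ba$loa_low)
  expect_gt(ba$loa_low_ci[2], ba$loa_low)
})

test_that("limits of agreement match lognormal theory in simulation", {
  # pairs with true log-ratio mean 0.05 and sd 0.3: the fitted limits
  # should concentrate around 0.05 +/- 1.96 * 0.3
  set.seed(55)
  lims <- t(vapply(1:500, function(i) {
    x <- exp(rnorm(59, -3.5, 0.9))
    y <- x / exp(rnorm(59, 0.05, 0.3))
    ba <- bland_altman_log(x, y)
    c(ba$loa_low, ba$loa_high)
  }, numeric(2)))
  expect_equal(mean(lims[, 1]), 0.05 - 1.96 * 0.3, tolerance = 0.02)
  expect_equal(mean(lims[, 2]), 0.05 + 1.96 * 0.3, tolerance = 0.02)
})

test_that("log-scale prediction interval matches its closed form", {
  expect_equal(unlist(prediction_interval_log(rep(0.03, 5))[c("low", "high")]),
               c(low = 0.03, high = 0.03))
  set.seed(10)
  v <- exp(rnorm(10, log(0.03), 0.5))
  pi_ <- prediction_interval_log(v)
  lv <- log(v)
  half <- qt(0.975, 9) * sd(lv) * sqrt(1 + 1 / 10)
  expect_equal(pi_$low, exp(mean(lv) - half), tolerance = 1e-12)
  expect_equal(pi_$high, exp(mean(lv) + half), tolerance = 1e-12)
  # the interval always contains the geometric mean
  expect_lt(pi_$low, exp(mean(lv)))
  expect_gt(pi_$high, exp(mean(lv)))
  expect_error(prediction_interval_log(c(0.1, -0.1, 0.2)), "positive")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(17)
  coh <- generate_cohort(seed = 17)
  pat <- coh[coh$group == "patient", ]
  labels <- pat$his_vis_pct >= 5
  ours <- roc_auc(pat$alpha, labels)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, pat$alpha,
                                                         quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("diagnostic report reproduces structure and strong coupling", {
  coh <- generate_cohort(seed = 2)
  rep_ <- diagnostic_report(coh)
  expect_s3_class(rep_, "diagnostic_report")
  expect_equal(nrow(rep_$roc_vis), 3)
  expect_equal(nrow(rep_$roc_morph), 3)
  # generator couples alpha to fat through the latent fraction: AUCs are
  # uniformly strong, and high on average, across cohort draws
  aucs <- vapply(1:10, function(s) {
    r <- diagnostic_report(generate_cohort(seed = 200 + s))
    c(r$roc_vis$auc, r$roc_morph$auc)
  }, numeric(6))
  expect_true(all(aucs > 0.8))
  expect_true(all(rowMeans(aucs) > 0.9))
  expect_true(all(rep_$roc_vis$sens_ci_lower <= rep_$roc_vis$sensitivity))
  expect_true(all(rep_$roc_vis$spec_ci_upper >= rep_$roc_vis$specificity))
  expect_s3_class(rep_$agreement, "agreement_result")
  expect_s3_class(rep_$control_pi, "prediction_interval")
  expect_error(diagnostic_report(coh[, c("group", "alpha")]),
               "missing required column")
})

test_that("label permutation centres the AUC on 0.5", {
  set.seed(23)
  scores <- rnorm(40)
  labels <- rep(c(TRUE, FALSE), each = 20)
  aucs <- vapply(1:500, function(i) roc_auc(scores, sample(labels)),
                 numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("group comparison wrappers run on a full cohort", {
  coh <- generate_cohort(seed = 6)
  cmp <- compare_groups(coh)
  expect_equal(cmp$variable, c("bmi", "lic_mg_g", "alpha"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
})
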