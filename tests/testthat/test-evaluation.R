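test_that("AUC matches enumeration on worked examples", {
  expect_equal(compute_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))$auc, 0.75)
  expect_equal(compute_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1.0)
  expect_equal(compute_auc(c(0, 1, 0, 1), rep(0.3, 4))$auc, 0.5)
  expect_error(compute_auc(c(1, 1), c(0.2, 0.9)), "one outcome class")
})

test_that("AUC equals the brute-force pair-counting oracle", {
  set.seed(101)
  for (case in 1:20) {
    n <- sample(5:200, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    probs <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    expect_equal(compute_auc(labels, probs)$auc, brute_auc(labels, probs))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(7)
  labels <- rbinom(120, 1, 0.25)
  labels[1:2] <- c(0, 1)
  probs <- runif(120)
  a0 <- compute_auc(labels, probs)$auc
  expect_equal(compute_auc(labels, qlogis(probs))$auc, a0)
  expect_equal(compute_auc(labels, probs^3)$auc, a0)
})

test_that("bootstrap AUC CIs are seeded and bracket the point estimate", {
  set.seed(8)
  labels <- rbinom(300, 1, 0.2)
  probs <- plogis(2 * labels + rnorm(300))
  a1 <- compute_auc(labels, probs, ci = TRUE, B = 200, seed = 99)
  a2 <- compute_auc(labels, probs, ci = TRUE, B = 200, seed = 99)
  expect_identical(a1[c("ci_lower", "ci_upper")], a2[c("ci_lower", "ci_upper")])
  expect_lte(a1$ci_lower, a1$auc)
  expect_gte(a1$ci_upper, a1$auc)
})

test_that("calibration tables match hand enumeration and conserve the cohort", {
  # perfect predictions, two bins
  ct <- calibration_table(rep(c(0, 1), each = 5),
                          rep(c(0, 1), each = 5), n_bins = 2)
  expect_equal(ct$table$obs_prop, c(0, 1))
  expect_equal(ct$table$mean_pred, c(0, 1))

  # constant prediction at prevalence: one occupied bin
  labels <- c(1, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  ct2 <- calibration_table(labels, rep(0.2, 10), n_bins = 4)
  expect_equal(nrow(ct2$table), 1)
  expect_equal(ct2$table$obs_prop, mean(labels))

  # 8 printed (p, y) pairs, 4 equal-frequency bins: two records per bin
  p8 <- c(0.05, 0.10, 0.30, 0.35, 0.55, 0.60, 0.80, 0.95)
  y8 <- c(0, 0, 0, 1, 1, 0, 1, 1)
  ct3 <- suppressWarnings(calibration_table(y8, p8, n_bins = 4))  # sparse zoom
  expect_equal(ct3$table$n, rep(2L, 4))
  expect_equal(ct3$table$mean_pred, c(0.075, 0.325, 0.575, 0.875))
  expect_equal(ct3$table$obs_prop, c(0, 0.5, 0.5, 1))
})

test_that("calibration bins conserve totals on random cohorts", {
  set.seed(31)
  for (case in 1:10) {
    n <- sample(30:400, 1)
    labels <- rbinom(n, 1, runif(1, 0.1, 0.5))
    probs <- runif(n)
    tab <- calibration_table(labels, probs, n_bins = sample(3:10, 1))$table
    expect_equal(sum(tab$n), n)
    expect_equal(sum(tab$n * tab$obs_prop), sum(labels))
    expect_true(all(tab$obs_prop >= 0 & tab$obs_prop <= 1))
  }
})

test_that("calibration reduces bins with a warning when records are scarce", {
  warns <- capture_warnings(
    ct <- calibration_table(c(0, 1, 0), c(0.1, 0.8, 0.3), n_bins = 5))
  expect_true(any(grepl("reducing bins", warns)))
  expect_lte(nrow(ct$table), 3)
})

test_that("the 0-0.25 zoom table restricts to the low-probability range", {
  set.seed(12)
  labels <- rbinom(500, 1, 0.15)
  probs <- runif(500)
  ct <- calibration_table(labels, probs, n_bins = 5)
  expect_equal(sum(ct$zoom$n), sum(probs <= 0.25))
  expect_true(all(ct$zoom$mean_pred <= 0.25))
})

test_that("continuous NRI matches its defining enumeration", {
  # events move (+0.1, -0.05); nonevents (-0.1, -0.2)
  labels <- c(1, 1, 0, 0)
  ref <- c(0.30, 0.30, 0.30, 0.30)
  new <- c(0.40, 0.25, 0.20, 0.10)
  expect_equal(continuous_nri(labels, ref, new)$nri, 1.0)
  expect_equal(continuous_nri(labels, ref, ref)$nri, 0)
  # all events up, all nonevents down: the maximum of 2
  expect_equal(continuous_nri(labels, ref, c(0.4, 0.5, 0.1, 0.2))$nri, 2)
})

test_that("continuous NRI is antisymmetric and matches the oracle on random data", {
  set.seed(21)
  for (case in 1:10) {
    n <- sample(20:150, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    ref <- runif(n)
    new <- pmin(pmax(ref + rnorm(n, 0, 0.1), 0), 1)
    nri <- continuous_nri(labels, ref, new)$nri
    expect_equal(nri, enum_nri(labels, ref, new))
    expect_equal(continuous_nri(labels, new, ref)$nri, -nri)
  }
})

test_that("AMH summaries by age strata use closed boundaries and type-7 quantiles", {
  coh <- data.frame(age_years = c(25, 26, 27, 28, 30),
                    amh_ng_ml = c(1, 2, 3, 4, 5))
  tab <- amh_summary_by_age_strata(coh)
  expect_equal(tab$stratum, c("<=30", ">30-<=40", ">40"))
  # age 30 belongs to the youngest stratum
  expect_equal(tab$n, c(5L, 0L, 0L))
  expect_equal(tab$median[1], 3)
  expect_equal(tab$q25[1], 2)
  expect_equal(tab$q75[1], 4)
  # empty strata: n = 0 with undefined percentiles
  expect_true(all(is.na(tab$median[2:3])))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  labels <- rbinom(150, 1, 0.3)
  labels[1:2] <- c(0, 1)
  probs <- round(plogis(labels + rnorm(150)), 2)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                        direction = "<")))
  expect_equal(compute_auc(labels, probs)$auc, ref)
})
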