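test_that("lognormal quartile matching recovers the generating parameters", {
  ln <- lognormal_from_quartiles(3.14, 1.7, 5.4)
  expect_equal(unname(ln["meanlog"]), log(3.14))
  # the fit preserves the median exactly and the log-scale IQR width
  # (the printed quartiles themselves are not log-symmetric about the
  # median, so only their ratio is reproducible by a lognormal)
  q <- qlnorm(c(0.25, 0.5, 0.75), ln["meanlog"], ln["sdlog"])
  expect_equal(q[2], 3.14)
  expect_equal(q[3] / q[1], 5.4 / 1.7, tolerance = 1e-10)
  expect_error(lognormal_from_quartiles(1, 2, 3), "q25 < median")
})

test_that("generators are deterministic under a fixed seed", {
  c1 <- generate_class_conditional_cohort(n = 500, seed = 123)
  c2 <- generate_class_conditional_cohort(n = 500, seed = 123)
  expect_identical(c1, c2)
  m1 <- generate_mechanistic_cohort(n = 500, seed = 123)
  m2 <- generate_mechanistic_cohort(n = 500, seed = 123)
  expect_identical(m1$amh_ng_ml, m2$amh_ng_ml)
  expect_identical(m1$por, m2$por)
  expect_false(identical(generate_class_conditional_cohort(n = 500, seed = 124),
                         c1))
})

test_that("degenerate prevalence gives an all-negative cohort", {
  cfg <- class_conditional_config(prevalence = 0)
  coh <- generate_class_conditional_cohort(n = 200, config = cfg, seed = 1)
  expect_true(all(coh$por == 0))
})

test_that("class-conditional cohorts reproduce the configured block medians", {
  coh <- generate_class_conditional_cohort(n = 15241, seed = 20170101)
  med_no <- median(coh$amh_ng_ml[coh$por == 0])
  med_yes <- median(coh$amh_ng_ml[coh$por == 1])
  expect_lt(abs(med_no - 3.14) / 3.14, 0.05)
  expect_lt(abs(med_yes - 0.67) / 0.67, 0.05)
  q <- quantile(coh$amh_ng_ml[coh$por == 0], c(0.25, 0.75), names = FALSE)
  expect_lt(abs(q[1] - 1.7) / 1.7, 0.07)
  expect_lt(abs(q[2] - 5.4) / 5.4, 0.07)
  expect_lt(abs(mean(coh$por) - 2224 / 15241), 3 * sqrt(0.146 * 0.854 / 15241))
  expect_true(all(coh$age_years >= 20 & coh$age_years <= 45))
})

test_that("mechanistic cohorts hit the calibrated stratum medians", {
  coh <- generate_mechanistic_cohort(n = 10000, seed = 20170101)
  tab <- amh_summary_by_age_strata(coh)
  expect_lt(abs(tab$median[1] - 3.65) / 3.65, 0.05)
  expect_lt(abs(tab$median[2] - 2.26) / 2.26, 0.05)
  expect_lt(abs(tab$median[3] - 0.98) / 0.98, 0.10)  # sparsest stratum
})

test_that("mechanistic prevalence is calibrated by the solved intercept", {
  coh <- generate_mechanistic_cohort(n = 30000, seed = 55)
  target <- 2224 / 15241
  expect_lt(abs(mean(coh$por) - target),
            3 * sqrt(target * (1 - target) / 30000))
})

test_that("the sigma -> 0 limit collapses AMH onto the age median curve", {
  cfg <- mechanistic_config(sigma_log = 1e-9, calibrate = FALSE)
  coh <- generate_mechanistic_cohort(n = 200, config = cfg, seed = 9)
  gen <- attr(coh, "generator")
  a <- pmin(pmax(coh$age_years, 26), 42)
  expected <- exp(approx(cfg$knot_ages, cfg$knot_logmed, a)$y)
  expect_equal(coh$amh_ng_ml, expected, tolerance = 1e-6)
})

test_that("the analytic true DOR curve matches empirical threshold proportions", {
  coh <- generate_mechanistic_cohort(n = 30000, seed = 77)
  gen <- attr(coh, "generator")
  cfg <- gen$config
  # empirical: fraction of subjects near age a whose *true* probability >= tau
  eta <- gen$a0 + cfg$a_age * coh$age_years +
    cfg$a_lnamh * log(coh$amh_ng_ml + 0.01)
  p_true <- plogis(eta)
  for (a in c(30, 35, 40)) {
    sel <- abs(coh$age_years - a) < 0.5
    emp <- mean(p_true[sel] >= 0.15)
    expect_lt(abs(emp - true_dor_curve(gen, a)), 0.04)
  }
  mid <- true_dor_midpoint(gen)
  expect_equal(true_dor_curve(gen, mid), 0.5, tolerance = 1e-6)
})

test_that("stimulation-day decline reproduces the configured mean declines exactly", {
  expect_equal(apply_stimulation_day_decline(3.0, 6), 3.0 * (1 - 0.174))
  expect_equal(apply_stimulation_day_decline(3.0, 6), 2.478)
  expect_equal(apply_stimulation_day_decline(2.0, "hcg"), 2.0 * (1 - 0.497))
  expect_equal(apply_stimulation_day_decline(2.0, "hcg"), 1.006)
  expect_equal(apply_stimulation_day_decline(1.37, 2), 1.37)
  expect_error(apply_stimulation_day_decline(1, 4), "unknown sampling day")
})

test_that("stochastic decline preserves the mean and is seeded", {
  amh <- rep(2, 20000)
  d1 <- apply_stimulation_day_decline(amh, "hcg", mode = "stochastic", seed = 5)
  d2 <- apply_stimulation_day_decline(amh, "hcg", mode = "stochastic", seed = 5)
  expect_identical(d1, d2)
  expect_gt(sd(d1), 0)
  expect_lt(abs(mean(d1) - 2 * (1 - 0.497)), 0.01)
  expect_true(all(d1 >= 0 & d1 <= 2))
})

test_that("mean-mode decline leaves an AMH-monotone model's AUC unchanged", {
  coh <- generate_class_conditional_cohort(n = 4000, seed = 31)
  # AMH-only monotone score: decline is a rank-preserving rescaling
  fit <- suppressWarnings(fit_por_model(coh, por_model_spec("model1")))
  fit$beta[["age"]] <- 0
  cfg <- stimulation_decline_config(sd = 0)
  tab <- sensitivity_auc_by_sampling_day(fit, coh, cfg)
  expect_equal(tab$auc[tab$day == "6"], tab$auc[tab$day == "2"])
  expect_equal(tab$auc[tab$day == "hcg"], tab$auc[tab$day == "2"])
})

test_that("zero decline fractions give identical AUC across days", {
  coh <- generate_class_conditional_cohort(n = 2000, seed = 32)
  fit <- fit_por_model(coh, por_model_spec("model2"))
  cfg <- stimulation_decline_config(fractions = c("2" = 0, "6" = 0, "hcg" = 0),
                                    sd = 0.2)
  tab <- sensitivity_auc_by_sampling_day(fit, coh, cfg)
  expect_equal(tab$auc, rep(tab$auc[1], 3))
})

test_that("heterogeneous hCG-day decline strictly degrades discrimination", {
  coh <- generate_class_conditional_cohort(n = 8000, seed = 33)
  fit <- fit_por_model(coh, por_model_spec("model2"))
  tab <- sensitivity_auc_by_sampling_day(fit, coh, seed = 77)
  auc2 <- tab$auc[tab$day == "2"]
  expect_lt(tab$auc[tab$day == "hcg"], auc2)
  # degradation grows with the decline fraction
  expect_lt(tab$auc[tab$day == "hcg"], tab$auc[tab$day == "6"])
})

test_that("decline configuration validates its inputs", {
  expect_error(stimulation_decline_config(fractions = c("2" = 0.3, "6" = 0.1)))
  expect_error(stimulation_decline_config(fractions = c(0, 0.2)), "named")
})
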