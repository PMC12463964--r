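test_that("design matrices follow the declared column layouts", {
  # polynomial: quadratic age, cubic AMH, lower-order terms included
  X2 <- build_design(list(age_years = 30, amh_ng_ml = 2),
                     por_model_spec("model2"))
  expect_equal(unname(X2[1, ]), c(30, 900, 2, 4, 8))
  expect_equal(colnames(X2), c("age", "age2", "amh", "amh2", "amh3"))

  # continuous: identity features
  X1 <- build_design(list(age_years = 41, amh_ng_ml = 0.7),
                     por_model_spec("model1"))
  expect_equal(unname(X1[1, ]), c(41, 0.7))

  # categorical: reference bin dropped, indicators for upper bins
  s0 <- por_model_spec("model0", age_bins = 35, amh_bins = 1.1)
  X0 <- build_design(list(age_years = 33, amh_ng_ml = 0.9), s0)
  expect_equal(unname(X0[1, ]), c(0, 0))
  expect_equal(unname(build_design(list(age_years = 36, amh_ng_ml = 2), s0)[1, ]),
               c(1, 1))
  # values outside the bin range land in the outermost bin, no error
  s0b <- por_model_spec("model0", age_bins = c(30, 40), amh_bins = c(1, 3))
  Xout <- build_design(list(age_years = 59, amh_ng_ml = 20), s0b)
  expect_equal(unname(Xout[1, ]), c(0, 1, 0, 1))
})

test_that("invalid records and invalid specs are rejected", {
  expect_error(build_design(list(age_years = NA, amh_ng_ml = 1),
                            por_model_spec("model1")), "invalid record")
  expect_error(build_design(list(age_years = 30, amh_ng_ml = 2),
                            por_model_spec("model0")), "unresolved")
  expect_error(por_model_spec("model0", age_bins = c(40, 30)),
               "strictly increasing")
})

test_that("IRLS fit matches the grid-search MLE oracle on the toy cohort", {
  toy <- toy_cohort()
  fit <- suppressWarnings(
    fit_por_model(toy, por_model_spec("model1"), tol = 1e-10))
  X <- cbind(toy$age_years, toy$amh_ng_ml)
  beta_oracle <- grid_mle(X, toy$por)
  expect_equal(unname(fit$beta), beta_oracle, tolerance = 1e-3)
  # achieved log-likelihood agrees with direct evaluation at the oracle
  expect_equal(fit$log_likelihood, toy_loglik(beta_oracle, X, toy$por),
               tolerance = 1e-6)
})

test_that("degenerate inputs are refused with informative errors", {
  toy <- toy_cohort()
  toy$amh_ng_ml <- 2  # zero variance
  expect_error(suppressWarnings(fit_por_model(toy, por_model_spec("model1"))),
               "zero-variance")
  toy2 <- toy_cohort()
  toy2$por <- 0
  expect_error(suppressWarnings(fit_por_model(toy2, por_model_spec("model1"))),
               "single class")
})

test_that("complete separation is flagged, not silently returned", {
  sep <- data.frame(age_years = c(30, 31, 32, 40, 41, 42),
                    amh_ng_ml = c(4, 3.5, 3, 1, 0.8, 0.6),
                    por = c(0, 0, 0, 1, 1, 1))
  warns <- capture_warnings(
    fit <- fit_por_model(sep, por_model_spec("model1")))
  expect_true(any(grepl("separation", warns)))
  expect_false(fit$converged)
  expect_error(predict_por_probability(fit, sep), "did not converge")
  expect_length(predict_por_probability(fit, sep, force = TRUE), 6)
})

test_that("model nesting never decreases the in-sample log-likelihood", {
  coh <- generate_class_conditional_cohort(n = 800, seed = 42)
  ll <- vapply(c("model1", "model2"), function(m)
    fit_por_model(coh, por_model_spec(m))$log_likelihood, numeric(1))
  fit1 <- fit_por_model(coh, por_model_spec("model1"))
  expect_gte(ll[["model2"]], ll[["model1"]])
  expect_gte(ll[["model1"]], fit1$null_log_likelihood)
})

test_that("fitted probabilities are invariant to predictor centering", {
  coh <- generate_class_conditional_cohort(n = 500, seed = 11)
  f_raw <- fit_por_model(coh, por_model_spec("model2", center = FALSE),
                         tol = 1e-12)
  f_cen <- fit_por_model(coh, por_model_spec("model2", center = TRUE),
                         tol = 1e-12)
  expect_equal(predict_por_probability(f_raw, coh),
               predict_por_probability(f_cen, coh), tolerance = 1e-6)
})

test_that("predicted probabilities are strictly inside (0, 1)", {
  coh <- generate_class_conditional_cohort(n = 1000, seed = 5)
  fit <- fit_por_model(coh, por_model_spec("model2"))
  extreme <- data.frame(age_years = c(20, 45, 58), amh_ng_ml = c(25, 0, 0.01))
  p <- predict_por_probability(fit, extreme)
  expect_true(all(p > 0 & p < 1))
  # all-zero coefficients give p = 0.5 everywhere
  fit0 <- fit
  fit0$beta[] <- 0
  expect_equal(unname(predict_por_probability(fit0, extreme)), rep(0.5, 3))
})

test_that("model0 quintile bins are resolved from the training cohort", {
  coh <- generate_class_conditional_cohort(n = 2000, seed = 9)
  fit <- fit_por_model(coh, por_model_spec("model0"))
  expect_length(fit$spec$age_bins, 4)
  expect_length(fit$spec$amh_bins, 4)
  expect_equal(fit$spec$amh_bins,
               unname(quantile(coh$amh_ng_ml, c(0.2, 0.4, 0.6, 0.8))),
               tolerance = 1e-8)
  expect_length(fit$beta, 9)  # intercept + 4 + 4 indicators
})

test_that("POR model JSON round trip preserves predictions", {
  coh <- generate_class_conditional_cohort(n = 500, seed = 3)
  fit <- fit_por_model(coh, por_model_spec("model2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_por_model(fit, path)
  fit2 <- read_por_model(path)
  expect_equal(predict_por_probability(fit2, coh),
               predict_por_probability(fit, coh))
  expect_equal(fit2$log_likelihood, fit$log_likelihood)
})
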