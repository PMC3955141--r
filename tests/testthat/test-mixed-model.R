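test_that("profile-ML optimum matches a dense grid-search oracle", {
  mi <- tiny_model_input()
  fit <- fit_ancova(mi)
  z <- log10(mi$y1 / mi$y0)
  X <- cbind(1, mi$node)
  best_grid <- oracle_ancova_grid(z, X, mi$patient)
  expect_gte(fit$loglik + 1e-6, best_grid)
  # and the fit's own log-likelihood is reproduced by the oracle formula
  ll_at_fit <- oracle_ancova_loglik(z, X, mi$patient, fit$lambda, fit$sigma2)
  expect_equal(fit$loglik, ll_at_fit, tolerance = 1e-8)
})

test_that("fixed effects agree with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  cfg <- cohort_config_response(seed = 14, n_patients = 12)
  mi <- model_input_from_cohort(generate_cohort(cfg), "B", "suv_mean")
  fit <- fit_ancova(mi)
  d <- transform(mi, z = log10(y1 / y0))
  ref <- nlme::lme(z ~ node, random = ~ 1 | patient, data = d, method = "ML")
  expect_equal(unname(fit$beta), unname(nlme::fixef(ref)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-5)
  expect_equal(fit$sigma2, ref$sigma^2, tolerance = 1e-4)

  reml <- fit_ancova(mi, method = "REML")
  ref_reml <- nlme::lme(z ~ node, random = ~ 1 | patient, data = d,
                        method = "REML")
  expect_equal(unname(reml$beta), unname(nlme::fixef(ref_reml)),
               tolerance = 1e-4)
  expect_equal(reml$sigma2, ref_reml$sigma^2, tolerance = 1e-4)
  expect_equal(reml$loglik_obj, as.numeric(stats::logLik(ref_reml)),
               tolerance = 1e-5)
})

test_that("degenerate random effect is recovered at the boundary", {
  cfg <- cohort_config(n_patients = 150,
                       baseline_log10_mean_primary = 0.3,
                       baseline_log10_mean_node = 0.2,
                       baseline_log10_sd = 0.2,
                       beta0 = -0.10, beta1 = -0.05,
                       sigma_b2 = 0, sigma2 = 0.006,
                       retest_sd_log10 = 0.04, seed = 25)
  mi <- model_input_from_cohort(generate_cohort(cfg), "B", "suv_mean")
  fit <- fit_ancova(mi)
  expect_lt(fit$sigma_b2, 0.001)
  expect_lt(abs(unname(fit$beta[1]) + 0.10), 0.02)
  expect_lt(abs(unname(fit$beta[2]) + 0.05), 0.03)
})

test_that("estimates are invariant to a common rescaling of y0 and y1", {
  mi <- tiny_model_input()
  f1 <- fit_ancova(mi)
  mi2 <- transform(mi, y0 = 7.3 * y0, y1 = 7.3 * y1)
  f2 <- fit_ancova(mi2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$sigma_b2, f2$sigma_b2, tolerance = 1e-6)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-6)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-6)
})

test_that("AIC counts four parameters for the two-effect model", {
  mi <- tiny_model_input()
  fit <- fit_ancova(mi)
  expect_equal(fit$k, 4L)
  expect_equal(fit$aic, -2 * fit$loglik + 8)
})

test_that("back-transformation reproduces the reported effect sizes", {
  expect_equal(back_transform_effect(-0.127), -25.355, tolerance = 1e-3)
  expect_equal(back_transform_effect(0), 0)
  expect_equal(back_transform_effect(-0.119 - 0.147), -45.80, tolerance = 1e-2)
})

test_that("effect CIs back-transform Wald endpoints and are asymmetric", {
  ci <- effect_ci(-0.127, 0.025)
  expect_equal(ci$lower, back_transform_effect(-0.127 - stats::qnorm(0.975) * 0.025))
  expect_equal(ci$upper, back_transform_effect(-0.127 + stats::qnorm(0.975) * 0.025))
  expect_lt(ci$lower, ci$point); expect_gt(ci$upper, ci$point)
  # symmetric on log scale; 10^x is convex, so the upper gap is wider
  expect_gt(ci$upper - ci$point, ci$point - ci$lower)

  ci0 <- effect_ci(-0.127, 1e-12)
  expect_equal(ci0$lower, ci0$point, tolerance = 1e-6)
  expect_equal(ci0$upper, ci0$point, tolerance = 1e-6)

  cit <- effect_ci(-0.127, 0.025, df = 28)
  expect_lt(cit$lower, ci$lower)              # t interval is wider
})

test_that("variance partition matches the reported shares", {
  expect_equal(variance_partition(0.00224, 0.00556), 0.2872, tolerance = 1e-4)
  expect_equal(variance_partition(0, 5), 0)
  expect_equal(variance_partition(3, 3), 0.5)
  expect_error(variance_partition(-1, 1), "nonnegative")
  expect_error(variance_partition(0, 0), "positive")
})

test_that("BED covariate extension reports the AIC comparison", {
  cfg <- cohort_config_response(seed = 33, n_patients = 60)
  mi <- model_input_from_cohort(generate_cohort(cfg), "B", "suv_mean")
  set.seed(1)
  mi$bed <- stats::runif(nrow(mi), 60, 80)    # unrelated covariate
  both <- fit_ancova_with_covariate(mi, "bed")
  expect_equal(both$extended$k, 5L)
  expect_gt(both$delta_aic, -2)               # no real improvement

  mi2 <- mi
  mi2$y1 <- mi2$y1 * 10^(-0.02 * (mi2$bed - 70))  # strong true effect
  both2 <- fit_ancova_with_covariate(mi2, "bed")
  expect_lt(both2$delta_aic, 0)
  expect_lt(abs(unname(both2$extended$beta["bed"]) + 0.02), 0.005)

  mi$bed <- 70
  expect_warning(res <- fit_ancova_with_covariate(mi, "bed"), "constant")
  expect_null(res$extended)
  expect_true(is.na(res$delta_aic))
})

test_that("single-lesion patients flag an unidentifiable random effect", {
  cfg <- cohort_config(n_patients = 10,
                       nodes_per_patient_range = c(0, 0),
                       baseline_log10_mean_primary = 0.3,
                       baseline_log10_mean_node = 0.2,
                       baseline_log10_sd = 0.2,
                       sigma2 = 0.005, retest_sd_log10 = 0.04, seed = 2)
  mi <- model_input_from_cohort(generate_cohort(cfg), "B", "suv_mean")
  fit <- fit_ancova(mi)                       # primaries only: beta1 dropped
  expect_true(fit$beta1_dropped)
  expect_true(fit$boundary)
  expect_false(fit$random_effect_identifiable)
  expect_equal(fit$k, 3L)
})

test_that("invalid model input is rejected", {
  mi <- tiny_model_input()
  bad <- mi; bad$y0[1] <- -1
  expect_error(fit_ancova(bad), "positive")
  one <- mi[mi$patient == "A", ]
  expect_error(fit_ancova(one), "2 patients")
})
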