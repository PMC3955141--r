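test_that("zero retest noise makes the duplicate baselines identical", {
  cfg <- cohort_config(n_patients = 5,
                       baseline_log10_mean_primary = 0.3,
                       baseline_log10_mean_node = 0.2,
                       baseline_log10_sd = 0.2,
                       retest_sd_log10 = 1e-12, seed = 7)
  coh <- generate_cohort(cfg)
  s1 <- coh[coh$scan_label == "S1", c("volume_cm3", "suv_mean", "suv_max")]
  s2 <- coh[coh$scan_label == "S2", c("volume_cm3", "suv_mean", "suv_max")]
  expect_equal(as.matrix(s1), as.matrix(s2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("null model is symmetric: mean log-ratio near zero", {
  cfg <- cohort_config(n_patients = 400,
                       baseline_log10_mean_primary = 0.3,
                       baseline_log10_mean_node = 0.2,
                       baseline_log10_sd = 0.2,
                       beta0 = 0, beta1 = 0, sigma_b2 = 0, sigma2 = 0.005,
                       retest_sd_log10 = 0.04, seed = 11)
  coh <- generate_cohort(cfg)
  mi <- model_input_from_cohort(coh, "B", "suv_mean")
  z <- log10(mi$y1 / mi$y0)
  # MC error ~ sqrt(0.005/1000) ~ 0.0022
  expect_lt(abs(mean(z)), 0.01)
})

test_that("node effect at response-model parameters matches the closed form", {
  # beta0 + beta1 = -0.222 on log10 scale => mean node effect 10^-0.222 - 1
  cfg <- cohort_config_response(seed = 21, n_patients = 500)
  coh <- generate_cohort(cfg)
  mi <- model_input_from_cohort(coh, "B", "suv_mean")
  z_node <- log10(mi$y1 / mi$y0)[mi$node == 1]
  emp <- mean(10^mean(z_node) - 1) * 100
  expect_equal(emp, (10^(-0.222) - 1) * 100, tolerance = 0.03)
  expect_lt(emp, -35); expect_gt(emp, -45)
})

test_that("fixed seed gives bit-identical cohorts; new seed differs", {
  cfg <- cohort_config_response(seed = 3)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config_response(seed = 4)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("config validation rejects degenerate inputs", {
  expect_error(cohort_config(0, baseline_log10_mean_primary = 0,
                             baseline_log10_mean_node = 0,
                             baseline_log10_sd = 0.1), "empty cohort")
  expect_error(cohort_config(3, baseline_log10_mean_primary = 0,
                             baseline_log10_mean_node = 0,
                             baseline_log10_sd = 0.1, sigma2 = 0),
               "sigma2")
  expect_error(cohort_config(3, nodes_per_patient_range = c(-1, 2),
                             baseline_log10_mean_primary = 0,
                             baseline_log10_mean_node = 0,
                             baseline_log10_sd = 0.1),
               "nodes_per_patient_range")
})

test_that("patient-mean residual variance converges to sigma_b2 + sigma2/m", {
  cfg <- cohort_config(n_patients = 2000,
                       nodes_per_patient_range = c(1, 1),
                       baseline_log10_mean_primary = 0.3,
                       baseline_log10_mean_node = 0.2,
                       baseline_log10_sd = 0.2,
                       beta0 = -0.1, beta1 = -0.05,
                       sigma_b2 = 0.003, sigma2 = 0.006,
                       retest_sd_log10 = 0.04, seed = 13)
  coh <- generate_cohort(cfg)
  mi <- model_input_from_cohort(coh, "B", "suv_mean")
  resid <- log10(mi$y1 / mi$y0) - (-0.1) - (-0.05) * mi$node
  pm <- tapply(resid, mi$patient, mean)       # m = 2 lesions per patient
  expect_equal(stats::var(pm), 0.003 + 0.006 / 2, tolerance = 0.12)
})

test_that("generated log-ratios are compatible with lognormality", {
  cfg <- cohort_config_response(seed = 5, n_patients = 60)
  coh <- generate_cohort(cfg)
  mi <- model_input_from_cohort(coh, "B", "suv_mean")
  z <- log10(mi$y1 / mi$y0)
  z <- z - ave(z, mi$node)                    # remove lesion-type means
  expect_gt(stats::shapiro.test(z)$p.value, 0.01)
})

test_that("survival generator recovers the designed hazard ratio", {
  cfg <- cohort_config_response(seed = 31, n_patients = 2000)
  coh <- generate_cohort(cfg)

  null_surv <- generate_survival(coh, link = 0, baseline_hazard = 0.05,
                                 censor_rate = 0.2, seed = 1)
  fit0 <- cox_univariate(null_surv$time_months, null_surv$event,
                         null_surv$covariate)
  expect_lt(abs(fit0$log_hr), 3 * fit0$se)

  surv2 <- generate_survival(coh, link = log(2), baseline_hazard = 0.05,
                             censor_rate = 0.2, seed = 2)
  fit2 <- cox_univariate(surv2$time_months, surv2$event, surv2$covariate)
  expect_gt(log(2), fit2$log_hr - 3 * fit2$se)
  expect_lt(log(2), fit2$log_hr + 3 * fit2$se)
  expect_equal(fit2$hr, 2, tolerance = 0.15)
})

test_that("full censoring yields no events and a Cox error", {
  cfg <- cohort_config_response(seed = 8, n_patients = 20)
  coh <- generate_cohort(cfg)
  s <- generate_survival(coh, link = 0, censor_rate = 1, seed = 3)
  expect_true(all(!s$event))
  expect_true(all(s$time_months > 0))
  expect_error(cox_univariate(s$time_months, s$event, s$covariate),
               "events")
})

test_that("survival generator validates the baseline hazard", {
  cfg <- cohort_config_response(seed = 8, n_patients = 5)
  coh <- generate_cohort(cfg)
  expect_error(generate_survival(coh, baseline_hazard = -1), "positive")
})
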