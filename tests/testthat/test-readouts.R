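noiseless_effects <- function() {
  effect_params(area_noise_sd = 0, procol_noise_sd = 0,
                mmp2_intensity_noise_sd = 0,
                asma_lognormal_params = c(meanlog = 0, sdlog = 0),
                tnmd_lognormal_params = c(meanlog = -3.5, sdlog = 0),
                mmp2_active_fraction_sd = 1e-9,
                release_intercept = 50)  # nobody releases
}

test_that("noiseless relative area is exactly affine in age and refittable", {
  co <- generate_cohort(cohort_params(n_patients = 30, seed = 5))
  ro <- generate_readouts(co, noiseless_effects(), seed = 6)
  expect_equal(ro$relative_area_pct, 28 + 0.96 * ro$age_y)
  fit <- fit_linear(model_input(ro, "relative_area_pct"))
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "age"], 0.96, tolerance = 1e-10)
  expect_equal(fit$fit_stat, 1, tolerance = 1e-10)
})

test_that("a strongly positive age effect on intactness saturates: no releases", {
  co <- generate_cohort(cohort_params(n_patients = 60, age_range = c(40, 60),
                                      mean_age = 48, sd_age = 5, seed = 4))
  e <- effect_params(release_age_coef = 5, release_intercept = -20)
  ro <- generate_readouts(co, e, seed = 9)
  expect_true(all(ro$intact == 1))
})

test_that("the calibrated intercept reproduces the 10/41 release rate", {
  e <- effect_params()
  ## Monte-Carlo oracle: released fraction over a very large cohort
  big <- generate_cohort(cohort_params(n_patients = 60000, seed = 12))
  ro <- generate_readouts(big, e, seed = 13)
  expect_lt(abs(mean(ro$intact == 0) - 10 / 41), 0.01)
  ## and at the n = 500 scale of the recovery studies, within 5 points
  co <- generate_cohort(cohort_params(n_patients = 440, seed = 11))
  ro2 <- generate_readouts(co, e, seed = 11)
  expect_lt(abs(mean(ro2$intact == 0) - 10 / 41), 0.05)
})

test_that("released tendons carry missing biochemical read-outs and a release time", {
  co <- generate_cohort(cohort_params(n_patients = 200, seed = 21))
  ro <- generate_readouts(co, effect_params(), seed = 22)
  rel <- ro[ro$intact == 0, ]
  expect_gt(nrow(rel), 0)
  for (col in c("pro_collagen_ng_ml", "tnmd_tubulin", "asma_tubulin",
                "active_mmp2_au", "mmp2_active_fraction", "tubulin_au")) {
    expect_true(all(is.na(rel[[col]])))
  }
  expect_true(all(rel$release_time_h >= 2 & rel$release_time_h <= 37))
  expect_true(all(!is.na(ro$relative_area_pct)))
  keep <- ro[ro$intact == 1, ]
  expect_true(all(!is.na(keep$pro_collagen_ng_ml)))
})

test_that("pro-collagen follows the plateau step: 5-fold drop around 25 years", {
  e <- effect_params(procol_noise_sd = 0, release_intercept = 50)
  expect_equal(e$procol_high_plateau / e$procol_low_plateau, 5, tolerance = 1e-6)
  co <- data.frame(patient_id = 1:2, tendon_id = 1:2, age_y = c(15, 45),
                   gender = c("M", "M"), tendon = c("ST", "ST"))
  ro <- generate_readouts(co, e, seed = 31)
  expect_gt(ro$pro_collagen_ng_ml[1] / ro$pro_collagen_ng_ml[2], 4.5)
})

test_that("read-outs are reproducible under a fixed seed", {
  co <- generate_cohort(cohort_params(seed = 2))
  e <- effect_params()
  expect_identical(generate_readouts(co, e, seed = 5),
                   generate_readouts(co, e, seed = 5))
})

test_that("effect parameter invariants are enforced", {
  expect_error(effect_params(procol_high_plateau = 10, procol_low_plateau = 50),
               "exceed")
  expect_error(effect_params(mmp2_active_fraction_mean = 0.05,
                             mmp2_active_fraction_sd = 0.05), "within")
})
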