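test_that("the Weir equation evaluates and stays linear", {
  expect_equal(weir_ee(0, 0), 0)
  expect_equal(weir_ee(1, 1), 4.597)
  expect_equal(weir_ee(0.3, 0.25), 1.3238)
  expect_error(weir_ee(-0.1, 0), ">=")
  # linearity in (vo2, vco2)
  set.seed(2)
  for (i in 1:10) {
    a <- runif(2); b <- runif(2); k <- runif(2, 0, 3)
    expect_equal(weir_ee(k[1] * a[1] + k[2] * b[1], k[1] * a[2] + k[2] * b[2]),
                 k[1] * weir_ee(a[1], a[2]) + k[2] * weir_ee(b[1], b[2]))
  }
})

test_that("the Freedson VM3 equation evaluates at hand-computed points", {
  expect_equal(freedson_vm3(0, 0), -5.500229)
  expect_equal(freedson_vm3(5170, 62.8), 5.4964046)
  # monotone in VM at fixed BW
  vm <- seq(0, 6e4, length.out = 50)
  expect_true(all(diff(freedson_vm3(vm, 70)) > 0))
})

test_that("RMR strategies behave as documented", {
  expect_equal(rmr_kcal_day("male", 30, 175, 70, equation = "constant:1400"),
               1400)
  # heavier body, higher RMR under both named equations
  for (eq in c("revised_harris_benedict", "mifflin_st_jeor")) {
    lo <- rmr_kcal_day("female", 25, 165, 55, equation = eq)
    hi <- rmr_kcal_day("female", 25, 165, 110, equation = eq)
    expect_gt(hi, lo)
  }
  expect_error(rmr_kcal_day("other", 25, 165, 55), "male")
  expect_error(rmr_kcal_day("male", 25, 165, 55, equation = "nope"), "Unknown")
  # predicted RMR at group-mean anthropometrics lands near the measured
  # group values (bioimpedance), within a 25% sanity band
  specs <- default_group_specs()
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    pred <- s$male_fraction *
      rmr_kcal_day("male", s$age_mean, s$height_cm_mean, s$weight_kg_mean) +
      (1 - s$male_fraction) *
      rmr_kcal_day("female", s$age_mean, s$height_cm_mean, s$weight_kg_mean)
    expect_lt(abs(pred - s$rmr_kcal_day_mean) / s$rmr_kcal_day_mean, 0.25)
  }
})

test_that("activity EE subtracts RMR per minute and floors at zero", {
  expect_equal(activity_ee(5.0, 1440), 4.0)
  expect_equal(activity_ee(3.2, 0), 3.2)
  expect_equal(activity_ee(0.5, 1440), 0)
})

test_that("body-weight normalisation inverts multiplication", {
  expect_equal(normalize_by_bw(6.9, 100), 0.069)
  expect_equal(normalize_by_bw(0, 70), 0)
  expect_equal(normalize_by_bw(0.12 * 63.7, 63.7), 0.12)
  expect_error(normalize_by_bw(1, 0), ">")
})

test_that("built-in model rows match the published coefficients", {
  pub <- published_model_rows()
  for (i in seq_len(nrow(pub))) {
    row <- ee_model_coefs(pub$model[i], pub$group[i])
    expect_equal(nrow(row), 1)
    expect_equal(row$intercept, pub$intercept[i])
    expect_equal(row$b_vm, pub$b_vm[i])
    expect_equal(row$b_bw, pub$b_bw[i])
    expect_equal(row$b_hrr, pub$b_hrr[i])
    expect_equal(row$output_units, "kcal/kg/min")
  }
  expect_equal(ee_model_coefs("freedson")$output_units, "kcal/min")
  expect_error(ee_model_coefs("modelC"), "Unknown")
  expect_error(ee_model_coefs("modelA", "XX"), "group")
})

test_that("model evaluation applies the linear form and guards HRR", {
  a_sg <- ee_model_coefs("modelA", "SG")
  expect_equal(model_ee(a_sg, 0, 0), 0.007852)
  expect_equal(model_ee(a_sg, 26000, 67.2), 0.1442296)
  b_sg <- ee_model_coefs("modelB", "SG")
  expect_error(model_ee(b_sg, 26000, 67.2), "HRR")
  # at hrr = 0 a Model B row reduces to its own non-HRR part
  expect_equal(model_ee(b_sg, 26000, 67.2, hrr = 0),
               b_sg$intercept + b_sg$b_vm * 26000 + b_sg$b_bw * 67.2)
  # linearity of the predictor part
  expect_equal(
    model_ee(b_sg, 2 * 26000, 2 * 67.2, hrr = 2 * 100) - b_sg$intercept,
    2 * (model_ee(b_sg, 26000, 67.2, hrr = 100) - b_sg$intercept))
})

test_that("stage estimates chain criterion and device formulas per group", {
  specs <- default_group_specs()
  roster <- simulate_cohort(specs, n_per_group = 2, seed = 6)
  epochs <- simulate_trials(roster, specs, noise_scale = 0.5, seed = 6)
  feats <- process_epochs(epochs, roster)
  est <- estimate_ee(feats, roster)
  expect_equal(nrow(est), nrow(feats))
  r1 <- dplyr::rename(roster, participant_id = id)
  j <- dplyr::left_join(est,
                        dplyr::select(r1, participant_id, rmr_kcal_day),
                        by = "participant_id")
  # criterion EE spot check on the first row
  i <- 1
  expect_equal(
    est$cm_ee_kcal_kg_min[i],
    (weir_ee(feats$vo2_lmin[i], feats$vco2_lmin[i]) -
       j$rmr_kcal_day[i] / 1440) / est$weight_kg[i])
  expect_equal(
    est$gt9x_ee_kcal_kg_min[i],
    freedson_vm3(feats$vm_per_min[i], est$weight_kg[i]) / est$weight_kg[i])
  # group-specific corrected models
  g <- est$group[i]
  expect_equal(
    est$model_b_ee_kcal_kg_min[i],
    model_ee(ee_model_coefs("modelB", g), est$vm_per_min[i],
             est$weight_kg[i], est$hrr_bpm[i]))
  # clamping applies only at the reporting layer
  est_cl <- estimate_ee(feats, roster, clamp_negative = TRUE)
  expect_true(all(est_cl$model_a_ee_kcal_kg_min >= 0))
})
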