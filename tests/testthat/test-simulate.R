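specs <- default_group_specs()
sg <- dplyr::filter(specs, group == "SG")

test_that("cohorts are deterministic under a fixed seed", {
  a <- generate_cohort(sg, n = 12, seed = 7)
  b <- generate_cohort(sg, n = 12, seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(sg, n = 12, seed = 8)
  expect_false(identical(a, c))
})

test_that("degenerate (zero-SD) specs return the group means", {
  r <- generate_cohort(zero_sd_spec("SG"), n = 1, seed = 1)
  expect_equal(r$age, sg$age_mean)
  expect_equal(r$height_cm, sg$height_cm_mean)
  expect_equal(r$weight_kg, sg$weight_kg_mean)
  expect_equal(r$hr_rest, sg$rest_hr_min)
})

test_that("cohort anthropometrics concentrate at the specified means", {
  r <- generate_cohort(sg, n = 30, seed = 1)
  expect_equal(nrow(r), 30)
  expect_lt(abs(mean(r$weight_kg) - 67.2), 3 * 13.9 / sqrt(30))
  expect_true(all(r$weight_kg >= 35))
  expect_true(all(r$hr_rest < 220 - r$age))
  expect_true(all(r$age >= 18))
  expect_error(generate_cohort(sg, n = 0), "positive")
})

test_that("trial generation is deterministic and schema-complete", {
  p <- generate_cohort(sg, 1, seed = 3)
  a <- generate_trial(p, sg, noise_scale = 1, seed = 11)
  b <- generate_trial(p, sg, noise_scale = 1, seed = 11)
  expect_identical(a, b)
  expect_setequal(
    names(a),
    c("participant_id", "stage_id", "speed_kmh", "t_start_s",
      "axis1", "axis2", "axis3", "hr_bpm", "vo2_lmin", "vco2_lmin"))
  expect_true(all(c("rest", as.character(1:5)) %in% a$stage_id))
  expect_true(all(a$axis1 >= 0 & a$axis2 >= 0 & a$axis3 >= 0))
  expect_true(all(a$vo2_lmin >= 0 & a$vco2_lmin >= 0))
  expect_true(all(diff(a$t_start_s) == 10))
})

test_that("noiseless trials invert exactly through the steady-state pipeline", {
  plan <- default_trial_plan()
  roster <- simulate_cohort(specs, n_per_group = 1, seed = 5)
  epochs <- simulate_trials(roster, specs, plan, noise_scale = 0, seed = 5)
  feats <- process_epochs(epochs, roster)
  est <- estimate_ee(feats, roster)
  ref <- tidyr::unnest(dplyr::select(specs, group, ee_profile), ee_profile)
  chk <- dplyr::left_join(est, ref, by = c("group", "speed_kmh"))
  expect_equal(nrow(chk), 20)  # 4 groups x 5 speeds
  expect_equal(chk$cm_ee_kcal_kg_min, chk$cmee_mean, tolerance = 1e-12)
  expect_equal(chk$gt9x_ee_kcal_kg_min, chk$gt9x_mean, tolerance = 1e-12)
  # HRR is the deterministic reserve fraction at noise 0
  roster1 <- dplyr::rename(roster, participant_id = id)
  hr_chk <- chk |>
    dplyr::left_join(dplyr::select(roster1, participant_id, age, hr_rest),
                     by = "participant_id")
  expect_equal(hr_chk$hrr_bpm,
               hr_chk$hrr_fraction * (220 - hr_chk$age - hr_chk$hr_rest),
               tolerance = 1e-10)
})

test_that("an EE target infeasible at the body weight is rejected", {
  spec <- zero_sd_spec("SG")
  prof <- spec$ee_profile[[1]]
  prof$gt9x_mean <- prof$gt9x_mean / 100  # far below the equation intercept
  prof$gt9x_sd <- 0
  spec$ee_profile <- list(prof)
  p <- generate_cohort(spec, 1, seed = 1)
  expect_error(generate_trial(p, spec, noise_scale = 0, seed = 1),
               class = "ankleEE_infeasible_spec")
})

test_that("group means at published SDs stay within sampling error of spec", {
  # per-speed sample means over repeated cohorts must sit within
  # 3 * SD / sqrt(n) of the specified means in at least 99% of generations
  plan <- default_trial_plan(rest_duration_s = 300)
  prof <- sg$ee_profile[[1]]
  n_seeds <- 100
  n <- 30
  hit_cm <- hit_gt <- matrix(NA, n_seeds, 5)
  for (s in seq_len(n_seeds)) {
    roster <- generate_cohort(sg, n = n, seed = s)
    epochs <- simulate_trials(roster, sg, plan, noise_scale = 1, seed = s)
    r1 <- dplyr::rename(roster, participant_id = id)
    means <- epochs |>
      dplyr::filter(stage_id != "rest") |>
      dplyr::group_by(participant_id, stage_id, speed_kmh) |>
      dplyr::mutate(.i = dplyr::row_number(), .n = dplyr::n()) |>
      dplyr::filter(.i > 12, .i <= .n - 1) |>
      dplyr::summarise(vo2 = mean(vo2_lmin), vco2 = mean(vco2_lmin),
                       vm = mean(sqrt(axis1^2 + axis2^2 + axis3^2)) * 6,
                       .groups = "drop") |>
      dplyr::left_join(dplyr::select(r1, participant_id, weight_kg,
                                     rmr_kcal_day),
                       by = "participant_id") |>
      dplyr::mutate(
        cm = (3.491 * vo2 + 1.106 * vco2 - rmr_kcal_day / 1440) / weight_kg,
        gt = (0.001064 * vm + 0.087512 * weight_kg - 5.500229) / weight_kg) |>
      dplyr::group_by(speed_kmh) |>
      dplyr::summarise(cm = mean(cm), gt = mean(gt), .groups = "drop") |>
      dplyr::arrange(speed_kmh)
    hit_cm[s, ] <- abs(means$cm - prof$cmee_mean) <= 3 * prof$cmee_sd / sqrt(n)
    hit_gt[s, ] <- abs(means$gt - prof$gt9x_mean) <= 3 * prof$gt9x_sd / sqrt(n)
  }
  expect_true(all(colMeans(hit_cm) >= 0.99))
  expect_true(all(colMeans(hit_gt) >= 0.99))
})

test_that("design tables from known coefficients support exact recovery", {
  coefs <- ee_model_coefs("modelB", "SG")
  d <- generate_from_model(coefs, n = 200, noise_sd = 0, seed = 2)
  expect_true(all(d$vm >= 2e4 & d$vm <= 6e4))
  expect_true(all(d$bw >= 45 & d$bw <= 100))
  expect_true(all(d$hrr >= 40 & d$hrr <= 160))
  fit <- lm(ee ~ vm + bw + hrr, data = d)
  expect_equal(unname(coef(fit)),
               c(coefs$intercept, coefs$b_vm, coefs$b_bw, coefs$b_hrr),
               tolerance = 1e-8)
  # square system: as many rows as coefficients interpolates exactly
  d4 <- generate_from_model(coefs, n = 4, noise_sd = 0, seed = 3)
  fit4 <- lm(ee ~ vm + bw + hrr, data = d4)
  expect_equal(unname(fitted(fit4)), d4$ee, tolerance = 1e-9)
  expect_error(generate_from_model(coefs, n = 3), "at least")
  expect_identical(generate_from_model(coefs, 10, 0.01, seed = 9),
                   generate_from_model(coefs, 10, 0.01, seed = 9))
})
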