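#' Generate a synthetic cohort for one fitness group
#'
#' Draws participant anthropometrics from truncated normal distributions at
#' the group's published means and SDs (truncated at mean +/- 3 SD and at
#' physical floors: age >= 18 y, height >= 140 cm, weight >= 35 kg), assigns
#' sex by the group's male fraction, draws resting HR uniformly over the
#' group's resting range, and computes a predicted resting metabolic rate
#' with the configured RMR equation.
#'
#' @param spec One row of [default_group_specs()] (or a compatible tibble).
#' @param n Number of participants (>= 1).
#' @param seed Optional integer seed; identical seeds give identical cohorts.
#' @param rmr_equation RMR prediction strategy passed to [rmr_kcal_day()].
#' @return A roster tibble with columns `id`, `group`, `sex`, `age`,
#'   `height_cm`, `weight_kg`, `hr_rest`, `rmr_kcal_day`.
#' @seealso [simulate_cohort()] for all groups at once.
#' @export
generate_cohort <- function(spec, n = 30, seed = NULL,
                            rmr_equation = "revised_harris_benedict") {
  spec <- as_tibble(spec)
  if (nrow(spec) != 1) abort("`spec` must be a single group row.")
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a positive count.")
  }
  n <- as.integer(n)
  local_seed(seed, {
    age <- rtrunc_norm(n, spec$age_mean, spec$age_sd,
                       lower = max(18, spec$age_mean - 3 * spec$age_sd),
                       upper = spec$age_mean + 3 * spec$age_sd)
    height <- rtrunc_norm(n, spec$height_cm_mean, spec$height_cm_sd,
                          lower = max(140, spec$height_cm_mean - 3 * spec$height_cm_sd),
                          upper = spec$height_cm_mean + 3 * spec$height_cm_sd)
    weight <- rtrunc_norm(n, spec$weight_kg_mean, spec$weight_kg_sd,
                          lower = max(35, spec$weight_kg_mean - 3 * spec$weight_kg_sd),
                          upper = spec$weight_kg_mean + 3 * spec$weight_kg_sd)
    n_male <- round(n * spec$male_fraction)
    sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
    hr_rest <- round(runif(n, spec$rest_hr_min, spec$rest_hr_max))
    tibble(
      id = sprintf("%s-%02d", spec$group, seq_len(n)),
      group = spec$group,
      sex = sex,
      age = age,
      height_cm = height,
      weight_kg = weight,
      hr_rest = hr_rest,
      rmr_kcal_day = rmr_kcal_day(sex, age, height, weight,
                                  equation = rmr_equation)
    )
  })
}

#' Generate a synthetic cohort for every group
#'
#' @param specs Group specification tibble, usually [default_group_specs()].
#' @param n_per_group Participants per group (default 30, the reference
#'   cohort size).
#' @inheritParams generate_cohort
#' @return A roster tibble (see [generate_cohort()]) with all groups stacked.
#' @export
simulate_cohort <- function(specs = default_group_specs(), n_per_group = 30,
                            seed = NULL,
                            rmr_equation = "revised_harris_benedict") {
  purrr::map2_dfr(
    seq_len(nrow(specs)), split(specs, seq_len(nrow(specs))),
    function(i, spec) {
      generate_cohort(spec, n = n_per_group,
                      seed = if (is.null(seed)) NULL else seed + i,
                      rmr_equation = rmr_equation)
    }
  )
}

#' Simulate one participant's treadmill trial at epoch resolution
#'
#' Produces a 10-s-epoch sensor stream emulating a seated rest period
#' followed by the plan's treadmill stages. For each stage the generator
#' draws a participant-level target criterion EE and accelerometer EE
#' (kcal/kg/min) from the group's per-speed distributions (correlated
#' within the cell by the spec's `ee_correlation`, both truncated at
#' +/- 3 SD), then constructs epoch signals that reproduce those targets
#' through the analysis pipeline:
#'
#' * breath-gas channels are obtained by inverting the Weir equation at a
#'   respiratory quotient drawn uniformly in \[0.85, 1.00\], after adding the
#'   participant's RMR back and un-normalising by body weight;
#' * triaxial counts are obtained by inverting the Freedson VM3 equation at
#'   the participant's body weight (counts/min scale) and splitting the
#'   vector magnitude over the axes in a fixed 2:1:2 direction;
#' * heart rate follows `HRrest + fraction * (220 - age - HRrest)` with the
#'   stage's reserve fraction, plus epoch jitter.
#'
#' The first 120 s of each stage ramp linearly from 60% to 100% of the
#' steady-state target (a warm-up transient that the steady-state trimmer
#' must discard), and the rest period ends with 5 min whose minimum HR is
#' exactly the participant's resting HR. `noise_scale` scales every random
#' component: 0 gives deterministic streams whose steady-state values equal
#' the group means exactly, 1 reproduces the published between-subject SDs.
#'
#' @param participant One roster row (see [generate_cohort()]).
#' @param spec The participant's group row from [default_group_specs()].
#' @param plan An `ee_trial_plan`, e.g. [default_trial_plan()].
#' @param noise_scale Non-negative multiplier on all random components.
#' @param seed Optional integer seed.
#' @return An epoch tibble with columns `participant_id`, `stage_id`
#'   (`"rest"` or the stage number), `speed_kmh`, `t_start_s`, `axis1`,
#'   `axis2`, `axis3`, `hr_bpm`, `vo2_lmin`, `vco2_lmin`.
#' @export
generate_trial <- function(participant, spec, plan = default_trial_plan(),
                           noise_scale = 1, seed = NULL) {
  p <- as.list(as_tibble(participant)[1, ])
  spec <- as_tibble(spec)
  stopifnot(inherits(plan, "ee_trial_plan"))
  check_number(noise_scale, "noise_scale", min = 0)
  prof <- spec$ee_profile[[1]]
  stages <- plan$stages
  if (!all(stages$speed_kmh %in% prof$speed_kmh)) {
    abort("Trial plan has speeds absent from the group's EE profile.")
  }
  el <- plan$epoch_length_s
  rmr_min <- p$rmr_kcal_day / 1440

  local_seed(seed, {
    blocks <- vector("list", nrow(stages) + 1)

    # --- rest period: HR decays onto HRrest; gas at resting metabolic rate
    n_rest <- plan$rest_duration_s / el
    t_rest <- seq(0, by = el, length.out = n_rest)
    tail_start <- plan$rest_duration_s - 300
    settle <- pmax(0, 1 - t_rest / max(tail_start, el))
    hr <- p$hr_rest + 15 * settle +
      abs(rnorm(n_rest, 0, 1.5 * noise_scale)) * (t_rest >= tail_start)
    hr[n_rest] <- p$hr_rest  # anchors the last-5-min minimum exactly
    rq0 <- 0.85
    vo2_rest <- rmr_min / (3.491 + 1.106 * rq0)
    g_jit <- pmax(0, 1 + rnorm(n_rest, 0, 0.02 * noise_scale))
    ax_rest <- abs(matrix(rnorm(3 * n_rest, 0, 15 * noise_scale), ncol = 3))
    blocks[[1]] <- tibble(
      participant_id = p$id, stage_id = "rest", speed_kmh = 0,
      t_start_s = t_rest,
      axis1 = ax_rest[, 1], axis2 = ax_rest[, 2], axis3 = ax_rest[, 3],
      hr_bpm = hr, vo2_lmin = vo2_rest * g_jit,
      vco2_lmin = rq0 * vo2_rest * g_jit
    )

    t0 <- plan$rest_duration_s
    for (i in seq_len(nrow(stages))) {
      row <- prof[prof$speed_kmh == stages$speed_kmh[i], ]
      dur <- stages$duration_s[i]
      n_ep <- dur / el

      # Correlated standard-normal pair: both EE measures are driven by the
      # same workload, so a high-expenditure participant also accumulates
      # high counts. Truncated at +/-3 to keep targets physiological.
      rho <- if ("ee_correlation" %in% names(spec)) spec$ee_correlation else 0.95
      z_cm <- rtrunc_norm(1, 0, 1, -3, 3)
      z_gt <- min(3, max(-3, rho * z_cm + sqrt(1 - rho^2) * rnorm(1)))
      cm_t <- max(1e-3, row$cmee_mean + noise_scale * row$cmee_sd * z_cm)
      gt_t <- max(1e-3, row$gt9x_mean + noise_scale * row$gt9x_sd * z_gt)
      rq <- runif(1, 0.85, 1.00)

      vo2_ss <- (cm_t * p$weight_kg + rmr_min) / (3.491 + 1.106 * rq)
      vm_min <- (gt_t * p$weight_kg - 0.087512 * p$weight_kg + 5.500229) /
        0.001064
      if (vm_min < 0) {
        abort(paste0(
          "Accelerometer EE target implies negative counts at this body ",
          "weight; the group specification is infeasible."),
          class = "ankleEE_infeasible_spec")
      }
      vm_epoch <- vm_min * el / 60

      j <- seq_len(n_ep)
      ramp_n <- ceiling(120 / el)
      f <- ifelse(j <= ramp_n, 0.6 + 0.4 * j / ramp_n, 1)
      g_jit <- pmax(0, 1 + rnorm(n_ep, 0, 0.02 * noise_scale))
      v_jit <- pmax(0, 1 + rnorm(n_ep, 0, 0.02 * noise_scale))
      vm_j <- vm_epoch * f * v_jit
      hr_target <- p$hr_rest + row$hrr_fraction * (220 - p$age - p$hr_rest)
      hr_j <- pmax(30, p$hr_rest + f * (hr_target - p$hr_rest) +
                     rnorm(n_ep, 0, 2 * noise_scale))

      blocks[[i + 1]] <- tibble(
        participant_id = p$id, stage_id = as.character(i),
        speed_kmh = stages$speed_kmh[i],
        t_start_s = t0 + (j - 1) * el,
        axis1 = vm_j * 2 / 3, axis2 = vm_j * 1 / 3, axis3 = vm_j * 2 / 3,
        hr_bpm = hr_j,
        vo2_lmin = vo2_ss * f * g_jit,
        vco2_lmin = rq * vo2_ss * f * g_jit
      )
      t0 <- t0 + dur
    }
    bind_rows(blocks)
  })
}

#' Simulate treadmill trials for a whole roster
#'
#' @param roster Roster tibble from [simulate_cohort()] / [generate_cohort()].
#' @param specs Group specification tibble covering every group in `roster`.
#' @inheritParams generate_trial
#' @return Epoch tibble for all participants (see [generate_trial()]).
#' @export
simulate_trials <- function(roster, specs = default_group_specs(),
                            plan = default_trial_plan(), noise_scale = 1,
                            seed = NULL) {
  missing <- setdiff(unique(roster$group), specs$group)
  if (length(missing) > 0) {
    abort(paste0("No specification for group(s): ",
                 paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(roster)), function(i) {
    generate_trial(roster[i, ], specs[specs$group == roster$group[i], ],
                   plan = plan, noise_scale = noise_scale,
                   seed = if (is.null(seed)) NULL else seed + 1000 + i)
  })
}

#' Generate a regression design table from known model coefficients
#'
#' Samples predictors uniformly over documented physiological ranges
#' (vector magnitude 20000--60000 counts/min, body weight 45--100 kg,
#' heart-rate reserve 40--160 bpm) and evaluates a linear EE model plus
#' Gaussian noise. Intended for parameter-recovery testing of the
#' calibration fitter.
#'
#' @param coefs A coefficient row, e.g. from [ee_model_coefs()].
#' @param n Number of rows (at least the number of model coefficients).
#' @param noise_sd SD of additive Gaussian noise on EE, in the model's
#'   output units.
#' @param seed Optional integer seed.
#' @return Tibble with columns `vm`, `bw`, `hrr`, `ee`.
#' @export
generate_from_model <- function(coefs, n, noise_sd = 0, seed = NULL) {
  coefs <- as_tibble(coefs)
  n_par <- 3 + as.integer(!is.na(coefs$b_hrr))
  if (n < n_par) abort("`n` must be at least the number of coefficients.")
  check_number(noise_sd, "noise_sd", min = 0)
  local_seed(seed, {
    vm <- runif(n, 2e4, 6e4)
    bw <- runif(n, 45, 100)
    hrr <- runif(n, 40, 160)
    ee <- model_ee(coefs, vm, bw,
                   hrr = if (is.na(coefs$b_hrr)) NULL else hrr) +
      rnorm(n, 0, noise_sd)
    tibble(vm = vm, bw = bw, hrr = hrr, ee = ee)
  })
}
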