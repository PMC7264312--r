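#' Reference cohort specifications for the four fitness groups
#'
#' Returns the published group-level statistical structure used by the
#' synthetic treadmill-trial generator: anthropometrics (mean and SD of age,
#' height, body weight, plus the male fraction) and, nested per group, the
#' per-speed distributions of criterion energy expenditure (CM-EE, indirect
#' calorimetry) and of ankle-accelerometer EE predicted by the Freedson VM3
#' combination equation (GT9X-EE), both in kcal/kg/min.
#'
#' The four groups are sedentary (SG), exercise-habit (EHG), non-endurance
#' athlete (NEG) and endurance athlete (EG). The five treadmill speeds are
#' 4.8, 6.4, 8.0, 9.7 and 11.3 km/h (3--7 mph).
#'
#' Heart-rate structure is not published at stage level, so the HR columns
#' are package defaults: each stage carries a heart-rate-reserve fraction
#' (`hrr_fraction`, the fraction of `220 - age - HRrest` reached at that
#' speed; 0.35/0.45/0.55/0.68/0.80 across the speeds, shifted down by 0.05
#' for the athlete groups) and each group a plausible resting-HR range, lower
#' for athletes.
#'
#' Within a speed cell the criterion-EE and accelerometer-EE targets of a
#' participant are drawn with correlation `ee_correlation` (default 0.95):
#' both measures respond to the same workload, so a participant who expends
#' more than the group mean also accumulates more counts. Setting it to 0
#' makes the two draws independent.
#'
#' @return A tibble with one row per group and columns
#'   `group`, `male_fraction`, `age_mean`, `age_sd`, `height_cm_mean`,
#'   `height_cm_sd`, `weight_kg_mean`, `weight_kg_sd`, `rmr_kcal_day_mean`,
#'   `rmr_kcal_day_sd`, `rest_hr_min`, `rest_hr_max`, `ee_correlation`, and
#'   a list-column
#'   `ee_profile` of per-speed tibbles with columns `speed_kmh`, `cmee_mean`,
#'   `cmee_sd`, `gt9x_mean`, `gt9x_sd`, `hrr_fraction`.
#' @seealso [generate_cohort()], [generate_trial()], [default_trial_plan()]
#' @export
#' @examples
#' specs <- default_group_specs()
#' specs$ee_profile[[1]]
default_group_specs <- function() {
  profile <- function(cmee_m, cmee_s, gt_m, gt_s, athlete) {
    frac <- c(0.35, 0.45, 0.55, 0.68, 0.80) - if (athlete) 0.05 else 0
    tibble(
      speed_kmh = ee_speeds(),
      cmee_mean = cmee_m, cmee_sd = cmee_s,
      gt9x_mean = gt_m, gt9x_sd = gt_s,
      hrr_fraction = frac
    )
  }
  tibble(
    group = c("SG", "EHG", "NEG", "EG"),
    male_fraction = c(12, 14, 17, 19) / 30,
    age_mean = c(21.9, 21.7, 21.1, 20.9),
    age_sd = c(1.9, 1.6, 1.7, 1.7),
    height_cm_mean = c(166.9, 167.3, 171.2, 170.0),
    height_cm_sd = c(8.1, 8.5, 7.7, 5.8),
    weight_kg_mean = c(67.2, 64.6, 68.7, 59.8),
    weight_kg_sd = c(13.9, 12.6, 16.9, 8.0),
    rmr_kcal_day_mean = c(1414.1, 1464.2, 1591.1, 1490.0),
    rmr_kcal_day_sd = c(200.7, 206.9, 250.6, 160.0),
    rest_hr_min = c(62, 58, 52, 48),
    rest_hr_max = c(78, 74, 68, 64),
    ee_correlation = 0.95,
    ee_profile = list(
      profile(c(0.069, 0.106, 0.144, 0.169, 0.194),
              c(0.007, 0.012, 0.007, 0.011, 0.012),
              c(0.239, 0.352, 0.440, 0.522, 0.599),
              c(0.037, 0.067, 0.078, 0.093, 0.105), FALSE),
      profile(c(0.068, 0.111, 0.147, 0.168, 0.201),
              c(0.005, 0.010, 0.011, 0.011, 0.014),
              c(0.242, 0.358, 0.452, 0.535, 0.614),
              c(0.037, 0.057, 0.065, 0.082, 0.097), FALSE),
      profile(c(0.073, 0.125, 0.160, 0.188, 0.217),
              c(0.013, 0.012, 0.014, 0.018, 0.020),
              c(0.244, 0.349, 0.436, 0.506, 0.572),
              c(0.045, 0.072, 0.086, 0.090, 0.100), TRUE),
      profile(c(0.073, 0.117, 0.154, 0.180, 0.210),
              c(0.013, 0.016, 0.010, 0.010, 0.014),
              c(0.240, 0.355, 0.462, 0.545, 0.620),
              c(0.030, 0.051, 0.067, 0.086, 0.092), TRUE)
    )
  )
}

#' Treadmill speeds of the reference protocol
#'
#' @return Numeric vector of the five stage speeds in km/h.
#' @export
ee_speeds <- function() c(4.8, 6.4, 8.0, 9.7, 11.3)

#' Default treadmill trial plan
#'
#' One seated rest period followed by the five walking/running stages. Each
#' stage lasts at least three minutes; the default uses exactly 180 s so that
#' the steady-state trimming rule (drop the first 120 s and the last 10 s)
#' leaves 50 s of analysable data per stage.
#'
#' @param stage_duration_s Duration of every speed stage in seconds
#'   (default 180). Must be a positive multiple of `epoch_length_s`.
#' @param epoch_length_s Epoch length in seconds (default 10).
#' @param rest_duration_s Pre-test seated rest in seconds (default 1200,
#'   i.e. 20 min; resting HR is the minimum over the last 5 min).
#' @return A list of class `ee_trial_plan` with elements `stages` (tibble of
#'   `speed_kmh`, `duration_s`), `epoch_length_s` and `rest_duration_s`.
#' @export
default_trial_plan <- function(stage_duration_s = 180, epoch_length_s = 10,
                               rest_duration_s = 1200) {
  trial_plan(tibble(speed_kmh = ee_speeds(), duration_s = stage_duration_s),
             epoch_length_s = epoch_length_s,
             rest_duration_s = rest_duration_s)
}

#' Construct and validate a trial plan
#'
#' @param stages Tibble or data frame with columns `speed_kmh` (strictly
#'   increasing) and `duration_s` (positive multiples of the epoch length).
#' @inheritParams default_trial_plan
#' @return A validated list of class `ee_trial_plan`.
#' @export
trial_plan <- function(stages, epoch_length_s = 10, rest_duration_s = 1200) {
  stages <- as_tibble(stages)
  stopifnot(all(c("speed_kmh", "duration_s") %in% names(stages)))
  check_number(epoch_length_s, "epoch_length_s", min = 0, allow_zero = FALSE)
  check_number(rest_duration_s, "rest_duration_s", min = 0)
  if (nrow(stages) < 1) abort("A trial plan needs at least one stage.")
  if (any(diff(stages$speed_kmh) <= 0)) {
    abort("Stage speeds must be strictly increasing.")
  }
  bad <- stages$duration_s <= 0 | stages$duration_s %% epoch_length_s != 0
  if (any(bad)) {
    abort("Stage durations must be positive multiples of the epoch length.")
  }
  if (rest_duration_s %% epoch_length_s != 0) {
    abort("Rest duration must be a multiple of the epoch length.")
  }
  structure(
    list(stages = stages, epoch_length_s = epoch_length_s,
         rest_duration_s = rest_duration_s),
    class = "ee_trial_plan"
  )
}
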