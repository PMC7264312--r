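#' Pipeline configuration
#'
#' Collects the protocol constants and analysis switches in one validated
#' object: epoch length, the steady-state trimming rule (drop the first
#' 120 s and last 10 s of a stage, require at least 30 s of survivors), the
#' 70/30 calibration split, the RMR prediction equation, the ICC form, the
#' negative-EE reporting clamp and the significance level.
#'
#' @param epoch_length_s Epoch length in seconds (default 10).
#' @param trim_head_s Seconds trimmed from the head of each stage (120).
#' @param trim_tail_s Seconds trimmed from the tail of each stage (10).
#' @param min_steady_s Minimum surviving steady-state duration (30).
#' @param rest_duration_s Seated rest duration (1200).
#' @param split_fraction Training fraction for calibration fits (0.70).
#' @param seed Integer seed governing simulation and the split.
#' @param n_per_group Cohort size per group for simulation (30).
#' @param noise_scale Generator noise multiplier (1 = published SDs).
#' @param rmr_equation RMR strategy, see [rmr_kcal_day()].
#' @param icc_form `"agreement"` or `"consistency"`, see [icc_agreement()].
#' @param clamp_negative_ee Clamp negative EE in reports (TRUE).
#' @param alpha Significance level (0.05).
#' @return A list of class `ee_config`.
#' @export
ee_config <- function(epoch_length_s = 10, trim_head_s = 120,
                      trim_tail_s = 10, min_steady_s = 30,
                      rest_duration_s = 1200, split_fraction = 0.70,
                      seed = 1, n_per_group = 30, noise_scale = 1,
                      rmr_equation = "revised_harris_benedict",
                      icc_form = "agreement", clamp_negative_ee = TRUE,
                      alpha = 0.05) {
  check_number(epoch_length_s, "epoch_length_s", min = 0, allow_zero = FALSE)
  for (v in c(trim_head_s, trim_tail_s, min_steady_s, rest_duration_s)) {
    check_number(v, "trim/min/rest durations", min = 0)
  }
  if (split_fraction <= 0 || split_fraction >= 1) {
    abort("`split_fraction` must be in (0, 1).")
  }
  if (!icc_form %in% c("agreement", "consistency")) {
    abort('`icc_form` must be "agreement" or "consistency".')
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  structure(
    list(epoch_length_s = epoch_length_s, trim_head_s = trim_head_s,
         trim_tail_s = trim_tail_s, min_steady_s = min_steady_s,
         rest_duration_s = rest_duration_s, split_fraction = split_fraction,
         seed = seed, n_per_group = n_per_group, noise_scale = noise_scale,
         rmr_equation = rmr_equation, icc_form = icc_form,
         clamp_negative_ee = clamp_negative_ee, alpha = alpha),
    class = "ee_config")
}

epoch_cols <- function() {
  c(participant_id = "c", stage_id = "c", speed_kmh = "d", t_start_s = "d",
    axis1 = "d", axis2 = "d", axis3 = "d", hr_bpm = "d", vo2_lmin = "d",
    vco2_lmin = "d")
}

#' Read and write epoch-level CSV streams
#'
#' The interchange dialect is a UTF-8 CSV with header
#' `participant_id,stage_id,speed_kmh,t_start_s,axis1,axis2,axis3,hr_bpm,vo2_lmin,vco2_lmin`.
#' HR and gas columns may be empty (device-only recordings). Writing then
#' reading is lossless.
#'
#' @param path CSV file path.
#' @return `read_epochs()` returns an epoch tibble; `write_epochs()`
#'   returns `path` invisibly.
#' @export
read_epochs <- function(path) {
  spec <- epoch_cols()
  out <- readr::read_csv(path, col_types = paste(spec, collapse = ""))
  missing <- setdiff(names(spec), names(out))
  if (length(missing) > 0) {
    abort(paste0("Epoch file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    abort(paste0("Unparseable epoch rows (first at line ", prob$row[1] + 1,
                 "): ", prob$expected[1]))
  }
  for (ax in c("axis1", "axis2", "axis3")) {
    bad <- which(!is.na(out[[ax]]) & out[[ax]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("Negative counts in `%s` (first at data row %d).",
                    ax, bad[1]))
    }
  }
  out
}

#' @param records Epoch tibble in the dialect above.
#' @rdname read_epochs
#' @export
write_epochs <- function(records, path) {
  records <- as_tibble(records)
  missing <- setdiff(names(epoch_cols()), names(records))
  if (length(missing) > 0) {
    abort(paste0("Epoch table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_csv(records[names(epoch_cols())], path)
  invisible(path)
}

#' Read and write cohort roster CSVs
#'
#' Columns: `id`, `group`, `sex`, `age`, `height_cm`, `weight_kg`,
#' `hr_rest`, `rmr_kcal_day`.
#'
#' @param path CSV file path.
#' @return `read_roster()` returns a roster tibble; `write_roster()`
#'   returns `path` invisibly.
#' @export
read_roster <- function(path) {
  out <- readr::read_csv(path, col_types = "cccddddd")
  need <- c("id", "group", "sex", "age", "height_cm", "weight_kg",
            "hr_rest", "rmr_kcal_day")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    abort(paste0("Roster is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out
}

#' @param roster Roster tibble.
#' @rdname read_roster
#' @export
write_roster <- function(roster, path) {
  readr::write_csv(as_tibble(roster), path)
  invisible(path)
}

#' Fit group-wise calibration models from stage estimates
#'
#' Reshapes an estimate table into the fitter's design columns and fits one
#' Model A (`EE ~ VM + BW`) or Model B (`EE ~ VM + BW + HRR`) per group
#' with the configured 70/30 split.
#'
#' @param estimates Estimate tibble from [estimate_ee()].
#' @param with_hrr Include the HRR term (Model B)?
#' @param split_fraction,seed,stratify Passed to [fit_linear_ee()]; the
#'   per-group seed is offset by the group index for independent splits.
#' @return Named list of `ee_fit` objects, one per group.
#' @export
fit_group_models <- function(estimates, with_hrr = FALSE,
                             split_fraction = 0.7, seed = NULL,
                             stratify = TRUE) {
  estimates <- as_tibble(estimates)
  design <- estimates |>
    rename(vm = vm_per_min, bw = weight_kg, hrr = hrr_bpm,
           ee = cm_ee_kcal_kg_min)
  groups <- unique(design$group)
  fits <- purrr::map(seq_along(groups), function(i) {
    fit_linear_ee(filter(design, group == groups[i]), with_hrr = with_hrr,
                  split_fraction = split_fraction,
                  seed = if (is.null(seed)) NULL else seed + i,
                  stratify = stratify)
  })
  setNames(fits, groups)
}

#' Run the full simulate-process-estimate-fit-validate pipeline
#'
#' Simulates a cohort and its treadmill trials (unless a roster and epoch
#' table are supplied), reduces the epochs to steady-state stage features,
#' computes criterion and predicted EE, fits de-novo Model A/B calibrations
#' per group, and scores the Freedson VM3 equation and the corrected
#' models against the criterion. When `out_dir` is given, writes
#' `roster.csv`, `epochs.csv`, `stage_features.csv`, `estimates.csv`,
#' `fitted_models.json`, `agreement_<model>.csv` and a `run_log.json`
#' capturing the configuration, seed and package versions.
#'
#' @param config An [ee_config()].
#' @param roster,epochs Optional pre-existing inputs (tibbles or CSV
#'   paths); both must be given together. Omit to simulate.
#' @param specs Group specifications used for simulation.
#' @param plan Trial plan used for simulation.
#' @param out_dir Optional output directory (created if needed).
#' @param write_epochs_file Also write the (large) epoch stream when
#'   `out_dir` is set (default `FALSE`).
#' @return A list: `roster`, `epochs`, `features`, `estimates`, `fits_a`,
#'   `fits_b`, `agreement` (named list of `ee_agreement` tibbles for
#'   `gt9x`, `model_a`, `model_b`, `fitted_a`, `fitted_b`), `config`.
#' @export
run_pipeline <- function(config = ee_config(), roster = NULL, epochs = NULL,
                         specs = default_group_specs(),
                         plan = default_trial_plan(
                           epoch_length_s = config$epoch_length_s,
                           rest_duration_s = config$rest_duration_s),
                         out_dir = NULL, write_epochs_file = FALSE) {
  stopifnot(inherits(config, "ee_config"))
  if (xor(is.null(roster), is.null(epochs))) {
    abort("Supply both `roster` and `epochs`, or neither (to simulate).")
  }
  if (is.null(roster)) {
    roster <- simulate_cohort(specs, n_per_group = config$n_per_group,
                              seed = config$seed,
                              rmr_equation = config$rmr_equation)
    epochs <- simulate_trials(roster, specs, plan = plan,
                              noise_scale = config$noise_scale,
                              seed = config$seed)
  } else {
    if (is.character(roster)) roster <- read_roster(roster)
    if (is.character(epochs)) epochs <- read_epochs(epochs)
  }

  features <- process_epochs(epochs, roster, config = config)
  estimates <- estimate_ee(features, roster)

  fits_a <- fit_group_models(estimates, with_hrr = FALSE,
                             split_fraction = config$split_fraction,
                             seed = config$seed)
  fits_b <- fit_group_models(estimates, with_hrr = TRUE,
                             split_fraction = config$split_fraction,
                             seed = config$seed)

  with_fitted <- estimates |>
    group_by(group) |>
    mutate(
      fitted_a_ee_kcal_kg_min = predict(
        fits_a[[group[1]]], tibble(vm = vm_per_min, bw = weight_kg)),
      fitted_b_ee_kcal_kg_min = predict(
        fits_b[[group[1]]],
        tibble(vm = vm_per_min, bw = weight_kg, hrr = hrr_bpm))
    ) |>
    ungroup()

  agreement <- lapply(
    setNames(nm = c("gt9x", "model_a", "model_b", "fitted_a", "fitted_b")),
    function(m) {
      agreement_table(with_fitted, model = m, icc_form = config$icc_form,
                      clamp_negative = config$clamp_negative_ee)
    })

  result <- list(roster = roster, epochs = epochs, features = features,
                 estimates = with_fitted, fits_a = fits_a, fits_b = fits_b,
                 agreement = agreement, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_roster(roster, file.path(out_dir, "roster.csv"))
    if (write_epochs_file) {
      write_epochs(epochs, file.path(out_dir, "epochs.csv"))
    }
    readr::write_csv(features, file.path(out_dir, "stage_features.csv"))
    readr::write_csv(with_fitted, file.path(out_dir, "estimates.csv"))
    all_fits <- bind_rows(
      purrr::imap(fits_a, ~ mutate(.x$coefficients, group = .y)),
      purrr::imap(fits_b, ~ mutate(.x$coefficients, group = .y)))
    write_ee_model(all_fits, file.path(out_dir, "fitted_models.json"))
    for (m in names(agreement)) {
      readr::write_csv(agreement[[m]],
                       file.path(out_dir, paste0("agreement_", m, ".csv")))
      jsonlite::write_json(agreement[[m]],
                           file.path(out_dir, paste0("agreement_", m, ".json")),
                           dataframe = "rows", na = "null", digits = NA)
    }
    log <- list(
      config = unclass(config),
      config_hash = rlang::hash(unclass(config)),
      package_version = as.character(utils::packageVersion("ankleEE")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}
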