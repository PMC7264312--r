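#' Criterion energy expenditure from breath gases (Weir equation)
#'
#' `EE (kcal/min) = 3.491 * VO2 + 1.106 * VCO2`, the abbreviated Weir
#' formula used by metabolic carts, which weights oxygen uptake and carbon
#' dioxide output to account for the fuel mix.
#'
#' @param vo2 Oxygen consumption in L/min (>= 0).
#' @param vco2 Carbon dioxide production in L/min (>= 0).
#' @return Total energy expenditure in kcal/min. Vectorised.
#' @export
#' @examples
#' weir_ee(0.3, 0.25)
weir_ee <- function(vo2, vco2) {
  check_number(vo2, "vo2", min = 0)
  check_number(vco2, "vco2", min = 0)
  3.491 * vo2 + 1.106 * vco2
}

#' Predicted resting metabolic rate
#'
#' RMR prediction from sex, age, height and weight. The equation is a
#' pluggable strategy:
#'
#' * `"revised_harris_benedict"` (default): the Roza--Shizgal revision of
#'   the Harris--Benedict equations;
#' * `"mifflin_st_jeor"`: the Mifflin--St Jeor equations;
#' * `"constant:<x>"`: returns `<x>` kcal/day for every subject (useful for
#'   controlled tests).
#'
#' @param sex `"male"` or `"female"` (recycled; ignored by `constant:`).
#' @param age Age in years.
#' @param height_cm Height in cm.
#' @param weight_kg Body weight in kg.
#' @param equation Strategy name, see above.
#' @return RMR in kcal/day. Vectorised over subjects.
#' @export
rmr_kcal_day <- function(sex, age, height_cm, weight_kg,
                         equation = "revised_harris_benedict") {
  if (grepl("^constant:", equation)) {
    value <- as.numeric(sub("^constant:", "", equation))
    if (!is.finite(value)) abort("Invalid constant RMR specification.")
    return(rep(value, max(length(sex), length(age), length(weight_kg))))
  }
  check_number(age, "age", min = 0, allow_zero = FALSE)
  check_number(height_cm, "height_cm", min = 0, allow_zero = FALSE)
  check_number(weight_kg, "weight_kg", min = 0, allow_zero = FALSE)
  if (any(!sex %in% c("male", "female"))) {
    abort('`sex` must be "male" or "female" for this RMR equation.')
  }
  male <- sex == "male"
  switch(
    equation,
    revised_harris_benedict = ifelse(
      male,
      88.362 + 13.397 * weight_kg + 4.799 * height_cm - 5.677 * age,
      447.593 + 9.247 * weight_kg + 3.098 * height_cm - 4.330 * age),
    mifflin_st_jeor = 10 * weight_kg + 6.25 * height_cm - 5 * age +
      ifelse(male, 5, -161),
    abort(sprintf("Unknown RMR equation '%s'.", equation))
  )
}

#' Activity-related energy expenditure
#'
#' Subtracts the resting metabolic rate (converted from kcal/day to
#' kcal/min with 1440 min/day) from a total EE value, flooring at 0.
#'
#' @param total_ee Total EE in kcal/min.
#' @param rmr RMR in kcal/day.
#' @return Activity EE in kcal/min (>= 0). Vectorised.
#' @export
activity_ee <- function(total_ee, rmr) {
  check_number(total_ee, "total_ee", min = 0)
  check_number(rmr, "rmr", min = 0)
  pmax(0, total_ee - rmr / 1440)
}

#' Normalise energy expenditure by body weight
#'
#' @param ee EE in kcal/min.
#' @param bw Body weight in kg (> 0).
#' @return EE in kcal/kg/min. Vectorised.
#' @export
normalize_by_bw <- function(ee, bw) {
  check_number(bw, "bw", min = 0, allow_zero = FALSE)
  ee / bw
}

#' Freedson VM3 combination equation
#'
#' The waist-calibrated count-based EE prediction
#' `EE (kcal/min) = 0.001064 * VM + 0.087512 * BW - 5.500229`, with VM in
#' counts per minute and BW in kg. Negative outputs (possible at very low
#' count rates) are preserved; clamp at the reporting layer if needed.
#'
#' @param vm Vector magnitude in counts/min (>= 0).
#' @param bw Body weight in kg (>= 0).
#' @return Predicted EE in kcal/min. Vectorised.
#' @export
#' @examples
#' freedson_vm3(5170, 62.8)
freedson_vm3 <- function(vm, bw) {
  check_number(vm, "vm", min = 0)
  check_number(bw, "bw", min = 0)
  0.001064 * vm + 0.087512 * bw - 5.500229
}

the_models <- new.env(parent = emptyenv())

#' Built-in EE model coefficient sets
#'
#' Loads the versioned JSON resource shipped with the package: the Freedson
#' VM3 combination equation (kcal/min) and the eight ankle-specific
#' corrected models (kcal/kg/min) -- Model A (`EE ~ VM + BW`) and Model B
#' (`EE ~ VM + BW + HRR`) for each of the four fitness groups.
#'
#' @param model `"freedson"`, `"modelA"` or `"modelB"`; `NULL` returns the
#'   full table.
#' @param group Group label (`"SG"`, `"EHG"`, `"NEG"`, `"EG"`) for the
#'   corrected models; `NULL` returns all groups of the requested model.
#' @return Coefficient tibble with columns `name`, `model`, `group`,
#'   `output_units`, `intercept`, `b_vm`, `b_bw`, `b_hrr` (NA when the
#'   model has no HRR term), `r_squared`, `see`.
#' @export
#' @examples
#' ee_model_coefs("modelA", "SG")
ee_model_coefs <- function(model = NULL, group = NULL) {
  if (is.null(the_models$table)) {
    path <- system.file("extdata", "ee_models.json", package = "ankleEE",
                        mustWork = TRUE)
    raw <- jsonlite::fromJSON(path)
    the_models$table <- as_tibble(raw$models)
  }
  out <- the_models$table
  if (!is.null(model)) {
    if (!model %in% out$model) abort(sprintf("Unknown model '%s'.", model))
    out <- out[out$model == model, ]
  }
  if (!is.null(group)) {
    out <- out[!is.na(out$group) & out$group == group, ]
    if (nrow(out) == 0) abort(sprintf("No coefficients for group '%s'.", group))
  }
  out
}

#' Evaluate a linear EE model
#'
#' `intercept + b_vm * vm + b_bw * bw (+ b_hrr * hrr)` in the model's
#' declared output units.
#'
#' @param coefs A single coefficient row (see [ee_model_coefs()] or
#'   [tidy()] of an `ee_fit`).
#' @param vm Vector magnitude in counts/min.
#' @param bw Body weight in kg.
#' @param hrr Heart-rate reserve in bpm; required iff the model has a
#'   `b_hrr` term.
#' @return Predicted EE in the model's output units. Vectorised.
#' @export
model_ee <- function(coefs, vm, bw, hrr = NULL) {
  coefs <- as_tibble(coefs)
  if (nrow(coefs) != 1) abort("`coefs` must be a single model row.")
  uses_hrr <- !is.na(coefs$b_hrr)
  if (uses_hrr && is.null(hrr)) {
    abort("This model includes an HRR term: supply `hrr`.")
  }
  out <- coefs$intercept + coefs$b_vm * vm + coefs$b_bw * bw
  if (uses_hrr) out <- out + coefs$b_hrr * hrr
  out
}

#' Per-stage EE estimates from steady-state features
#'
#' Combines the feature table with the roster to produce, per participant
#' and speed: criterion EE (Weir equation minus RMR, per kg), the Freedson
#' VM3 prediction per kg, and the group-specific corrected Model A and
#' Model B predictions.
#'
#' @param features Feature tibble from [process_epochs()].
#' @param roster Roster tibble (needs `id`, `group`, `weight_kg`,
#'   `rmr_kcal_day`).
#' @param clamp_negative If `TRUE`, clamp negative EE estimates to 0
#'   (reporting convention). Default `FALSE` preserves linearity for
#'   fitting.
#' @return Estimate tibble: `participant_id`, `group`, `speed_kmh`,
#'   `vm_per_min`, `hrr_bpm`, `weight_kg`, `cm_ee_kcal_kg_min`,
#'   `gt9x_ee_kcal_kg_min`, `model_a_ee_kcal_kg_min`,
#'   `model_b_ee_kcal_kg_min`.
#' @export
estimate_ee <- function(features, roster, clamp_negative = FALSE) {
  features <- as_tibble(features)
  roster <- as_tibble(roster)
  df <- left_join(features,
                  select(roster, id, group, weight_kg, rmr_kcal_day),
                  by = c(participant_id = "id"))
  if (any(is.na(df$weight_kg))) {
    abort("Some participants in `features` are missing from `roster`.")
  }
  out <- df |>
    group_by(group) |>
    mutate(
      cm_ee_kcal_kg_min = normalize_by_bw(
        activity_ee(weir_ee(vo2_lmin, vco2_lmin), rmr_kcal_day), weight_kg),
      gt9x_ee_kcal_kg_min = normalize_by_bw(
        freedson_vm3(vm_per_min, weight_kg), weight_kg),
      model_a_ee_kcal_kg_min = model_ee(
        ee_model_coefs("modelA", group[1]), vm_per_min, weight_kg),
      model_b_ee_kcal_kg_min = model_ee(
        ee_model_coefs("modelB", group[1]), vm_per_min, weight_kg,
        hrr = hrr_bpm)
    ) |>
    ungroup() |>
    select(participant_id, group, speed_kmh, vm_per_min, hrr_bpm, weight_kg,
           cm_ee_kcal_kg_min, gt9x_ee_kcal_kg_min,
           model_a_ee_kcal_kg_min, model_b_ee_kcal_kg_min)
  if (clamp_negative) {
    out <- mutate(out, across(dplyr::ends_with("_kcal_kg_min"),
                              ~ pmax(0, .x)))
  }
  out
}
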