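# Published validation-table values used as frozen expectations.

# Per group x speed: criterion and accelerometer EE (mean, SD; kcal/kg/min),
# published effect size and MAPE. `mape_consistent` marks whether the
# published MAPE agrees with its own group means (one tabulated cell does
# not: the self-consistent value for that cell is 222.52, not 225.52).
published_validation <- function() {
  tibble::tribble(
    ~group, ~speed_kmh, ~cm_m, ~cm_s, ~gt_m, ~gt_s, ~es, ~mape, ~mape_consistent,
    "SG",  4.8,  0.069, 0.007, 0.239, 0.037, 6.38, 246.38, TRUE,
    "SG",  6.4,  0.106, 0.012, 0.352, 0.067, 5.11, 232.08, TRUE,
    "SG",  8.0,  0.144, 0.007, 0.440, 0.078, 5.35, 205.56, TRUE,
    "SG",  9.7,  0.169, 0.011, 0.522, 0.093, 5.33, 208.88, TRUE,
    "SG", 11.3,  0.194, 0.012, 0.599, 0.105, 5.42, 208.76, TRUE,
    "EHG", 4.8,  0.068, 0.005, 0.242, 0.037, 6.59, 255.88, TRUE,
    "EHG", 6.4,  0.111, 0.010, 0.358, 0.057, 6.04, 225.52, FALSE,
    "EHG", 8.0,  0.147, 0.011, 0.452, 0.065, 6.54, 207.48, TRUE,
    "EHG", 9.7,  0.168, 0.011, 0.535, 0.082, 6.27, 218.45, TRUE,
    "EHG", 11.3, 0.201, 0.014, 0.614, 0.097, 5.96, 205.47, TRUE,
    "NEG", 4.8,  0.073, 0.013, 0.244, 0.045, 5.16, 234.25, TRUE,
    "NEG", 6.4,  0.125, 0.012, 0.349, 0.072, 4.34, 179.20, TRUE,
    "NEG", 8.0,  0.160, 0.014, 0.436, 0.086, 4.48, 172.50, TRUE,
    "NEG", 9.7,  0.188, 0.018, 0.506, 0.090, 4.90, 169.15, TRUE,
    "NEG", 11.3, 0.217, 0.020, 0.572, 0.100, 4.92, 163.59, TRUE,
    "EG",  4.8,  0.073, 0.013, 0.240, 0.030, 7.22, 228.77, TRUE,
    "EG",  6.4,  0.117, 0.016, 0.355, 0.051, 6.30, 203.42, TRUE,
    "EG",  8.0,  0.154, 0.010, 0.462, 0.067, 6.43, 200.00, TRUE,
    "EG",  9.7,  0.180, 0.010, 0.545, 0.086, 5.96, 202.78, TRUE,
    "EG", 11.3,  0.210, 0.014, 0.620, 0.092, 6.23, 195.24, TRUE
  )
}

# The eight published ankle-correction model rows, hard-coded independently
# of the package's JSON resource: intercept, VM, BW and (Model B) HRR terms,
# output in kcal/kg/min.
published_model_rows <- function() {
  tibble::tribble(
    ~model, ~group, ~intercept, ~b_vm, ~b_bw, ~b_hrr,
    "modelA", "SG",   0.007852, 0.000006, -0.000292, NA,
    "modelA", "EHG",  0.020757, 0.000006, -0.000419, NA,
    "modelA", "NEG", -0.005442, 0.000007, -0.000168, NA,
    "modelA", "EG",   0.007280, 0.000006, -0.000170, NA,
    "modelB", "SG",   0.012550, 0.000005, -0.000271, 0.000284,
    "modelB", "EHG",  0.031277, 0.000004, -0.000417, 0.000478,
    "modelB", "NEG",  0.021134, 0.000005, -0.000342, 0.000542,
    "modelB", "EG",   0.014313, 0.000005, -0.000200, 0.000304
  )
}

# Epoch block for a single synthetic stage with constant signal values.
flat_stage_epochs <- function(n_epochs, epoch_length = 10, axis = c(300, 100, 200),
                              hr = 150, vo2 = 1, vco2 = 0.9, stage_id = "1",
                              speed = 8.0, t0 = 0) {
  tibble::tibble(
    participant_id = "P1", stage_id = stage_id, speed_kmh = speed,
    t_start_s = t0 + (seq_len(n_epochs) - 1) * epoch_length,
    axis1 = axis[1], axis2 = axis[2], axis3 = axis[3],
    hr_bpm = hr, vo2_lmin = vo2, vco2_lmin = vco2
  )
}

# One-group spec with all SDs forced to zero (degenerate distributions).
zero_sd_spec <- function(group = "SG") {
  spec <- dplyr::filter(default_group_specs(), group == !!group)
  spec$age_sd <- 0
  spec$height_cm_sd <- 0
  spec$weight_kg_sd <- 0
  spec$rest_hr_max <- spec$rest_hr_min
  spec
}
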