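#' Vector magnitude of triaxial activity counts
#'
#' Euclidean norm `sqrt(axis1^2 + axis2^2 + axis3^2)` of the three axis
#' counts of an epoch. Vectorised over epochs.
#'
#' @param axis1,axis2,axis3 Non-negative activity counts per epoch.
#' @return Vector magnitude in counts per epoch.
#' @export
#' @examples
#' compute_vm(3, 4, 12)  # 13
compute_vm <- function(axis1, axis2, axis3) {
  check_number(axis1, "axis1", min = 0)
  check_number(axis2, "axis2", min = 0)
  check_number(axis3, "axis3", min = 0)
  sqrt(axis1^2 + axis2^2 + axis3^2)
}

#' Rescale a mean per-epoch vector magnitude to counts per minute
#'
#' Count-based EE equations are stated on the counts-per-minute scale while
#' epochs are typically 10 s; this applies the `60 / epoch_length` factor.
#'
#' @param mean_epoch_vm Mean vector magnitude per epoch (counts/epoch).
#' @param epoch_length_s Epoch length in seconds; must divide 60.
#' @return Counts per minute.
#' @export
vm_to_per_minute <- function(mean_epoch_vm, epoch_length_s) {
  check_number(epoch_length_s, "epoch_length_s", min = 0, allow_zero = FALSE)
  if (60 %% epoch_length_s != 0) {
    abort("`epoch_length_s` must divide 60.")
  }
  mean_epoch_vm * (60 / epoch_length_s)
}

#' Trim a stage to its steady-state window and summarise it
#'
#' Discards the metabolic transient at the head of a treadmill stage (first
#' 120 s by default) and a short synchronisation guard at the tail (last
#' 10 s), then aggregates the surviving epochs. A stage must retain at least
#' 30 s ("at least 30 s" is inclusive: exactly 30 s is kept); otherwise an
#' error of class `ankleEE_insufficient_steady` signals that the stage must
#' be excluded.
#'
#' @param stage_epochs Epoch tibble for one contiguous stage (columns
#'   `axis1`, `axis2`, `axis3`, `hr_bpm`, `vo2_lmin`, `vco2_lmin`, and
#'   optionally `stage_id`, `speed_kmh`).
#' @param epoch_length_s Epoch length in seconds.
#' @param trim_head_s,trim_tail_s Seconds removed from the head and tail
#'   (defaults 120 and 10); converted to epochs with `ceiling()`.
#' @param min_steady_s Minimum surviving duration in seconds (default 30).
#' @return One-row tibble: `stage_id`, `speed_kmh`, `n_epochs`,
#'   `duration_s`, `vm_per_min`, `vo2_lmin`, `vco2_lmin`, `hr_max_bpm`.
#' @export
trim_steady_state <- function(stage_epochs, epoch_length_s = 10,
                              trim_head_s = 120, trim_tail_s = 10,
                              min_steady_s = 30) {
  e <- as_tibble(stage_epochs)
  if ("stage_id" %in% names(e) && length(unique(e$stage_id)) > 1) {
    abort("`stage_epochs` must contain a single stage.")
  }
  if ("t_start_s" %in% names(e)) {
    dt <- diff(e$t_start_s)
    if (length(dt) > 0 && any(abs(dt - epoch_length_s) > 1e-9)) {
      abort("Stage epochs must be contiguous and aligned to the epoch grid.")
    }
  }
  drop_head <- ceiling(trim_head_s / epoch_length_s)
  drop_tail <- ceiling(trim_tail_s / epoch_length_s)
  keep <- seq_len(nrow(e)) > drop_head & seq_len(nrow(e)) <= nrow(e) - drop_tail
  if (sum(keep) * epoch_length_s < min_steady_s) {
    abort(sprintf(
      "Only %d s of steady-state data remain after trimming (>= %d s required).",
      sum(keep) * epoch_length_s, min_steady_s),
      class = "ankleEE_insufficient_steady")
  }
  w <- e[keep, ]
  tibble(
    stage_id = if ("stage_id" %in% names(w)) w$stage_id[1] else NA_character_,
    speed_kmh = if ("speed_kmh" %in% names(w)) w$speed_kmh[1] else NA_real_,
    n_epochs = nrow(w),
    duration_s = nrow(w) * epoch_length_s,
    vm_per_min = vm_to_per_minute(
      mean(compute_vm(w$axis1, w$axis2, w$axis3)), epoch_length_s),
    vo2_lmin = mean(w$vo2_lmin),
    vco2_lmin = mean(w$vco2_lmin),
    hr_max_bpm = max(w$hr_bpm)
  )
}

#' Resting heart rate from a seated rest recording
#'
#' The resting value is the minimum HR over the final 5 minutes of the rest
#' period.
#'
#' @param rest_epochs Epoch tibble for the rest period (columns `t_start_s`,
#'   `hr_bpm`).
#' @param epoch_length_s Epoch length in seconds.
#' @return Resting HR in bpm.
#' @export
resting_hr <- function(rest_epochs, epoch_length_s = 10) {
  e <- as_tibble(rest_epochs)
  span <- max(e$t_start_s) + epoch_length_s - min(e$t_start_s)
  if (span < 300) {
    abort("Rest period must cover at least 5 minutes.")
  }
  tail_from <- max(e$t_start_s) + epoch_length_s - 300
  min(e$hr_bpm[e$t_start_s >= tail_from])
}

#' Heart-rate reserve of a stage
#'
#' `HRR = HRmax - HRrest`, where `HRmax` is the maximum HR over the stage's
#' steady-state window. A negative difference is clamped to 0 with a
#' warning.
#'
#' @param window_hr Non-empty vector of HR values (bpm) in the window.
#' @param hr_rest Resting HR in bpm.
#' @return HRR in bpm (>= 0).
#' @export
stage_hrr <- function(window_hr, hr_rest) {
  if (length(window_hr) == 0) abort("`window_hr` must be non-empty.")
  hrr <- max(window_hr) - hr_rest
  if (hrr < 0) {
    warn("Stage HRmax below resting HR; clamping HRR to 0.")
    hrr <- 0
  }
  hrr
}

#' Age-predicted heart-rate safety limit
#'
#' @param age Age in years (> 0).
#' @return `220 - age` in bpm.
#' @export
hr_safety_limit <- function(age) {
  check_number(age, "age", min = 0, allow_zero = FALSE)
  220 - age
}

#' Does a heart-rate trace exceed the safety limit?
#'
#' Trials in which HR exceeds `220 - age` are excluded from analysis.
#'
#' @param hr HR values in bpm.
#' @param age Age in years.
#' @return `TRUE` if any value exceeds the limit.
#' @export
exceeds_safety <- function(hr, age) {
  any(hr > hr_safety_limit(age))
}

#' Reduce epoch streams to per-stage steady-state features
#'
#' For each participant: computes resting HR from the rest block, excludes
#' stages whose HR exceeds the safety limit (220 - age), trims every speed
#' stage to its steady-state window, and derives the stage heart-rate
#' reserve. Stages with insufficient steady-state data are dropped with a
#' warning.
#'
#' @param epochs Epoch tibble (see [generate_trial()] for the dialect).
#' @param roster Roster tibble providing `id` and `age` per participant.
#' @param config Pipeline configuration from [ee_config()].
#' @return Feature tibble: `participant_id`, `stage_id`, `speed_kmh`,
#'   `duration_s`, `vm_per_min`, `vo2_lmin`, `vco2_lmin`, `hr_max_bpm`,
#'   `hr_rest_bpm`, `hrr_bpm`.
#' @export
process_epochs <- function(epochs, roster, config = ee_config()) {
  epochs <- as_tibble(epochs)
  roster <- as_tibble(roster)
  missing <- setdiff(unique(epochs$participant_id), roster$id)
  if (length(missing) > 0) {
    abort(paste0("Participants present in epochs but absent from roster: ",
                 paste(missing, collapse = ", ")))
  }
  el <- config$epoch_length_s
  purrr::map_dfr(split(epochs, epochs$participant_id), function(pe) {
    age <- roster$age[roster$id == pe$participant_id[1]]
    rest <- pe[pe$stage_id == "rest", ]
    if (nrow(rest) == 0) {
      abort(sprintf("Participant %s has no rest block.", pe$participant_id[1]))
    }
    hr_rest <- resting_hr(rest, epoch_length_s = el)
    stages <- pe[pe$stage_id != "rest", ]
    purrr::map_dfr(split(stages, stages$stage_id), function(se) {
      if (exceeds_safety(se$hr_bpm, age)) {
        warn(sprintf(
          "Participant %s stage %s exceeds the HR safety limit; excluded.",
          se$participant_id[1], se$stage_id[1]))
        return(NULL)
      }
      win <- tryCatch(
        trim_steady_state(se, epoch_length_s = el,
                          trim_head_s = config$trim_head_s,
                          trim_tail_s = config$trim_tail_s,
                          min_steady_s = config$min_steady_s),
        ankleEE_insufficient_steady = function(cnd) {
          warn(sprintf("Participant %s stage %s: %s",
                       se$participant_id[1], se$stage_id[1],
                       conditionMessage(cnd)))
          NULL
        })
      if (is.null(win)) return(NULL)
      mutate(win,
             participant_id = se$participant_id[1],
             hr_rest_bpm = hr_rest,
             hrr_bpm = stage_hrr(win$hr_max_bpm, hr_rest),
             .before = 1)
    })
  })
}
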