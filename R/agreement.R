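#' Method-agreement table for a predicted-EE column
#'
#' Scores one prediction method against criterion EE at the granularity of
#' the reference validation tables: per group x speed, the paired t-test,
#' Cohen's d (pooled-SD form on the cell means/SDs) and MAPE; per group,
#' pooled across speeds at stage level, the Pearson correlation and the
#' intraclass correlation (rows with `speed = "pooled"`).
#'
#' @param estimates Estimate tibble from [estimate_ee()] (needs `group`,
#'   `speed_kmh`, `cm_ee_kcal_kg_min` and the requested model column).
#' @param model `"gt9x"` (Freedson VM3), `"model_a"` or `"model_b"`, or the
#'   name of any EE column in `estimates` (without the
#'   `_ee_kcal_kg_min` suffix).
#' @param icc_form ICC variant, see [icc_agreement()].
#' @param clamp_negative Clamp negative predictions to 0 before scoring
#'   (reporting convention; default `TRUE`).
#' @return A tibble of class `ee_agreement`: `group`, `speed` (character;
#'   `"pooled"` for the per-group rows), `n`, `mean_actual`, `sd_actual`,
#'   `mean_pred`, `sd_pred` (kcal/kg/min), `t_stat`, `p_value`, `es`,
#'   `mape_pct`, `pearson_r`, `icc`.
#' @export
agreement_table <- function(estimates, model = "gt9x",
                            icc_form = c("agreement", "consistency"),
                            clamp_negative = TRUE) {
  icc_form <- arg_match(icc_form)
  estimates <- as_tibble(estimates)
  pred_col <- paste0(model, "_ee_kcal_kg_min")
  if (!pred_col %in% names(estimates)) {
    abort(sprintf("Column `%s` not found in `estimates`.", pred_col))
  }
  df <- tibble(
    group = estimates$group,
    speed_kmh = estimates$speed_kmh,
    actual = estimates$cm_ee_kcal_kg_min,
    pred = estimates[[pred_col]]
  )
  if (clamp_negative) df$pred <- pmax(0, df$pred)

  per_cell <- df |>
    group_by(group, speed_kmh) |>
    summarise(
      n = dplyr::n(),
      mean_actual = mean(actual), sd_actual = sd(actual),
      mean_pred = mean(pred), sd_pred = sd(pred),
      t_stat = paired_t(pred, actual)$t_stat,
      p_value = paired_t(pred, actual)$p_value,
      es = cohens_d(mean(pred), sd(pred), mean(actual), sd(actual)),
      mape_pct = mape(pred, actual),
      .groups = "drop"
    ) |>
    mutate(speed = as.character(speed_kmh), pearson_r = NA_real_,
           icc = NA_real_) |>
    select(-speed_kmh)

  pooled <- df |>
    group_by(group) |>
    summarise(
      n = dplyr::n(),
      mean_actual = mean(actual), sd_actual = sd(actual),
      mean_pred = mean(pred), sd_pred = sd(pred),
      mape_pct = mape(pred, actual),
      pearson_r = pearson_r(actual, pred),
      icc = icc_agreement(cbind(actual, pred), form = icc_form),
      .groups = "drop"
    ) |>
    mutate(speed = "pooled", t_stat = NA_real_, p_value = NA_real_,
           es = NA_real_)

  out <- bind_rows(per_cell, pooled) |>
    select(group, speed, n, mean_actual, sd_actual, mean_pred, sd_pred,
           t_stat, p_value, es, mape_pct, pearson_r, icc) |>
    arrange(group, .data$speed == "pooled",
            suppressWarnings(as.numeric(.data$speed)))
  class(out) <- c("ee_agreement", class(out))
  attr(out, "model") <- model
  out
}

#' Render an agreement table as plain text
#'
#' Compact fixed-width layout (one row per group x speed, ICC on the pooled
#' row) for eyeball comparison with published validation tables.
#'
#' @param x An `ee_agreement` tibble.
#' @return A character vector of lines, invisibly; printed as a side
#'   effect.
#' @export
render_agreement_text <- function(x) {
  stopifnot(inherits(x, "ee_agreement"))
  hdr <- sprintf("%-5s %-7s %22s %22s %6s %9s %7s %7s",
                 "Group", "Speed", "Actual EE (kcal/kg/min)",
                 "Pred EE (kcal/kg/min)", "ES", "MAPE (%)", "r", "ICC")
  lines <- c(hdr, strrep("-", nchar(hdr)))
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    lines <- c(lines, sprintf(
      "%-5s %-7s %22s %22s %6s %9s %7s %7s",
      r$group, r$speed,
      sprintf("%.3f ± %.3f", r$mean_actual, r$sd_actual),
      sprintf("%.3f ± %.3f", r$mean_pred, r$sd_pred),
      ifelse(is.na(r$es), "", sprintf("%.2f", r$es)),
      sprintf("%.2f", r$mape_pct),
      ifelse(is.na(r$pearson_r), "", sprintf("%.3f", r$pearson_r)),
      ifelse(is.na(r$icc), "", sprintf("%.3f", r$icc))))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Plot group-mean EE against treadmill speed
#'
#' Mean +/- SD of criterion EE and one or more predicted-EE columns by
#' group and speed.
#'
#' @param estimates Estimate tibble from [estimate_ee()].
#' @param models Character vector of method prefixes to show alongside the
#'   criterion (default all present among `gt9x`, `model_a`, `model_b`).
#' @return A ggplot object.
#' @export
plot_ee_by_speed <- function(estimates,
                             models = c("gt9x", "model_a", "model_b")) {
  estimates <- as_tibble(estimates)
  cols <- c(cm = "cm_ee_kcal_kg_min",
            setNames(paste0(models, "_ee_kcal_kg_min"), models))
  cols <- cols[cols %in% names(estimates)]
  long <- estimates |>
    select(group, speed_kmh, dplyr::all_of(unname(cols))) |>
    tidyr::pivot_longer(-c(group, speed_kmh), names_to = "method",
                        values_to = "ee") |>
    mutate(method = sub("_ee_kcal_kg_min", "", .data$method)) |>
    group_by(group, speed_kmh, .data$method) |>
    summarise(mean = mean(.data$ee), sd = sd(.data$ee), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$speed_kmh, .data$mean,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             size = 0.2) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Treadmill speed (km/h)", y = "EE (kcal/kg/min)",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Agreement summary plot
#'
#' Per-speed MAPE bars by group, with the pooled ICC annotated per facet.
#'
#' @param object An `ee_agreement` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ee_agreement
#' @export
autoplot.ee_agreement <- function(object, ...) {
  cells <- filter(object, .data$speed != "pooled")
  pooled <- filter(object, .data$speed == "pooled")
  ggplot2::ggplot(cells, ggplot2::aes(.data$speed, .data$mape_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      data = pooled,
      ggplot2::aes(x = Inf, y = Inf,
                   label = sprintf("ICC = %.3f, r = %.3f", .data$icc,
                                   .data$pearson_r)),
      hjust = 1.05, vjust = 1.5, size = 3, inherit.aes = FALSE) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Treadmill speed (km/h)", y = "MAPE (%)",
                  title = paste0("Agreement with criterion EE: ",
                                 attr(object, "model"))) +
    ggplot2::theme_minimal()
}
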