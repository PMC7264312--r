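#' Fit a linear EE calibration model with 70/30 cross-validation
#'
#' Ordinary least squares of `ee ~ vm + bw` (Model A form) or
#' `ee ~ vm + bw + hrr` (Model B form) on a random training split, with the
#' held-out fraction used for validation. The split is seeded and, by
#' default, stratified by any `group` and `speed_kmh` columns present so
#' that every cell contributes to both halves.
#'
#' @param data Tibble with columns `ee` (response, typically kcal/kg/min),
#'   `vm` (counts/min), `bw` (kg), and `hrr` (bpm) when `with_hrr = TRUE`;
#'   optional `group` / `speed_kmh` columns drive stratification.
#' @param with_hrr Include the heart-rate-reserve term?
#' @param split_fraction Training fraction in (0, 1\]; `1` fits on all rows
#'   and skips validation.
#' @param seed Optional integer seed for the split.
#' @param stratify Stratify the split by `group` x `speed_kmh` when those
#'   columns are present (default `TRUE`).
#' @return An object of class `ee_fit`: the fitted coefficients, training
#'   `r_squared`, `see` (standard error of estimate,
#'   `sqrt(SSE / (n - p - 1))`), `n_train`, `n_test`, and held-out
#'   `validation_r` (Pearson) and `validation_icc` (absolute-agreement
#'   ICC). Supports [tidy()], [glance()], [predict()] and [autoplot()].
#' @export
#' @examples
#' dat <- generate_from_model(ee_model_coefs("modelA", "SG"), 60, 0.01,
#'                            seed = 1)
#' fit_linear_ee(dat, seed = 1)
fit_linear_ee <- function(data, with_hrr = FALSE, split_fraction = 0.7,
                          seed = NULL, stratify = TRUE) {
  data <- as_tibble(data)
  vars <- c("vm", "bw", if (with_hrr) "hrr")
  need <- c("ee", vars)
  if (!all(need %in% names(data))) {
    abort(paste0("`data` must contain columns: ", paste(need, collapse = ", ")))
  }
  if (anyNA(data[need])) abort("Missing values in response or predictors.")
  p <- length(vars)
  if (nrow(data) < p + 2) abort("Too few rows to fit the model.")
  if (split_fraction <= 0 || split_fraction > 1) {
    abort("`split_fraction` must be in (0, 1].")
  }

  idx_train <- local_seed(seed, {
    if (split_fraction == 1) {
      seq_len(nrow(data))
    } else {
      strata <- if (stratify) {
        keys <- intersect(c("group", "speed_kmh"), names(data))
        if (length(keys) > 0) {
          interaction(data[keys], drop = TRUE)
        } else {
          factor(rep(1, nrow(data)))
        }
      } else {
        factor(rep(1, nrow(data)))
      }
      unlist(lapply(split(seq_len(nrow(data)), strata), function(ix) {
        sample(ix, max(1, round(split_fraction * length(ix))))
      }), use.names = FALSE)
    }
  })
  train <- data[idx_train, ]
  test <- data[-idx_train, ]

  fml <- stats::reformulate(vars, response = "ee")
  fit <- lm(fml, data = train)
  if (fit$rank < p + 1) {
    abort("Rank-deficient design: predictors are collinear.",
          class = "ankleEE_rank_deficient")
  }
  sm <- summary(fit)
  cf <- coef(fit)
  coefs <- tibble(
    name = if (with_hrr) "fitted_modelB" else "fitted_modelA",
    model = if (with_hrr) "modelB" else "modelA",
    group = if ("group" %in% names(data) &&
                length(unique(data$group)) == 1) data$group[1] else NA_character_,
    output_units = "kcal/kg/min",
    intercept = unname(cf["(Intercept)"]),
    b_vm = unname(cf["vm"]),
    b_bw = unname(cf["bw"]),
    b_hrr = if (with_hrr) unname(cf["hrr"]) else NA_real_,
    r_squared = sm$r.squared,
    see = sm$sigma
  )

  validation_r <- NA_real_
  validation_icc <- NA_real_
  if (nrow(test) >= 3) {
    pred <- predict(fit, newdata = test)
    validation_r <- pearson_r(test$ee, pred)
    validation_icc <- icc_agreement(cbind(test$ee, pred))
  }

  structure(
    list(coefficients = coefs, lm = fit, with_hrr = with_hrr,
         r_squared = sm$r.squared, see = sm$sigma,
         n_train = nrow(train), n_test = nrow(test),
         validation_r = validation_r, validation_icc = validation_icc),
    class = "ee_fit"
  )
}

#' @export
print.ee_fit <- function(x, ...) {
  cat("EE calibration fit (", x$coefficients$model, ")\n", sep = "")
  eq <- sprintf("EE = %.6f x VM %+.6f x BW", x$coefficients$b_vm,
                x$coefficients$b_bw)
  if (x$with_hrr) eq <- sprintf("%s %+.6f x HRR", eq, x$coefficients$b_hrr)
  eq <- sprintf("%s %+.6f  [%s]", eq, x$coefficients$intercept,
                x$coefficients$output_units)
  cat(" ", eq, "\n", sep = "")
  cat(sprintf("  R^2 = %.3f, SEE = %.4f (n_train = %d)\n",
              x$r_squared, x$see, x$n_train))
  if (x$n_test > 0) {
    cat(sprintf("  validation (n = %d): r = %.3f, ICC = %.3f\n",
                x$n_test, x$validation_r, x$validation_icc))
  }
  invisible(x)
}

#' Tidy an EE calibration fit
#'
#' @param x An `ee_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy ee_fit
#' @export
tidy.ee_fit <- function(x, ...) {
  cm <- summary(x$lm)$coefficients
  tibble(
    term = rownames(cm),
    estimate = cm[, "Estimate"],
    std.error = cm[, "Std. Error"],
    statistic = cm[, "t value"],
    p.value = cm[, "Pr(>|t|)"]
  )
}

#' One-row summary of an EE calibration fit
#'
#' @param x An `ee_fit` object.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `see`, `n_train`, `n_test`,
#'   `validation_r`, `validation_icc`.
#' @method glance ee_fit
#' @export
glance.ee_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, see = x$see,
    n_train = x$n_train, n_test = x$n_test,
    validation_r = x$validation_r, validation_icc = x$validation_icc
  )
}

#' Predict from an EE calibration fit
#'
#' @param object An `ee_fit`.
#' @param newdata Tibble with `vm`, `bw` (and `hrr` for a Model B fit).
#' @param ... Unused.
#' @return Predicted EE in the fit's output units.
#' @export
predict.ee_fit <- function(object, newdata, ...) {
  unname(predict(object$lm, newdata = as_tibble(newdata)))
}

#' Calibration scatter plot for an EE calibration fit
#'
#' Model predictions on the training split against observed criterion EE,
#' with the identity line.
#'
#' @param object An `ee_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ee_fit
#' @export
autoplot.ee_fit <- function(object, ...) {
  dat <- tibble(
    observed = object$lm$model$ee,
    predicted = stats::fitted(object$lm)
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "Criterion EE (kcal/kg/min)", y = "Predicted EE (kcal/kg/min)",
      title = sprintf("%s: R² = %.3f, SEE = %.4f",
                      object$coefficients$model, object$r_squared,
                      object$see)
    ) +
    ggplot2::theme_minimal()
}

#' Write / read EE model coefficients as JSON
#'
#' Fitted models and built-in coefficient sets share one JSON schema
#' (`name`, `model`, `group`, `output_units`, coefficient fields, fit
#' metadata), so fitted calibrations can be re-used wherever a built-in
#' model is accepted.
#'
#' @param x An `ee_fit` or a coefficient tibble row.
#' @param path File path.
#' @return `write_ee_model()` returns `path` invisibly; `read_ee_model()`
#'   returns a coefficient tibble usable with [model_ee()].
#' @export
write_ee_model <- function(x, path) {
  coefs <- if (inherits(x, "ee_fit")) x$coefficients else as_tibble(x)
  payload <- list(schema = "ankleEE/model-coefficients", version = "1.0",
                  models = coefs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_ee_model
#' @export
read_ee_model <- function(path) {
  raw <- jsonlite::fromJSON(path)
  out <- as_tibble(raw$models)
  if (!"b_hrr" %in% names(out)) out$b_hrr <- NA_real_
  out$b_hrr[vapply(out$b_hrr, is.null, logical(1))] <- NA_real_
  out$b_hrr <- as.numeric(out$b_hrr)
  out
}
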