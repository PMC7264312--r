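#' Mean absolute percentage error
#'
#' `MAPE = mean(|predicted - actual| / |actual|) * 100`, computed per
#' observation then averaged.
#'
#' @param predicted,actual Equal-length numeric vectors; `actual` must be
#'   nonzero everywhere.
#' @return MAPE in percent (>= 0).
#' @export
#' @examples
#' mape(c(0.239), c(0.069))
mape <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    abort("`predicted` and `actual` must have equal length.")
  }
  if (any(actual == 0)) abort("`actual` contains zero values.")
  mean(abs(predicted - actual) / abs(actual)) * 100
}

#' Cohen's d from group summary statistics
#'
#' Pooled-SD, equal-n form: `|mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)`.
#' This is the variant consistent with the reference validation tables.
#'
#' @param mean1,sd1 Mean and SD of the first condition.
#' @param mean2,sd2 Mean and SD of the second condition.
#' @return Effect size (>= 0). `Inf` with a warning when both SDs are zero
#'   but the means differ.
#' @export
#' @examples
#' cohens_d(0.239, 0.037, 0.069, 0.007)
cohens_d <- function(mean1, sd1, mean2, sd2) {
  check_number(sd1, "sd1", min = 0)
  check_number(sd2, "sd2", min = 0)
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (pooled == 0) {
    if (mean1 == mean2) {
      warn("Both SDs are zero with equal means; effect size set to 0.")
      return(0)
    }
    warn("Both SDs are zero with distinct means; effect size is infinite.")
    return(Inf)
  }
  abs(mean1 - mean2) / pooled
}

#' Paired t-test
#'
#' Classical paired t statistic with a two-sided p-value and `df = n - 1`.
#' Zero-variance differences are degenerate: the statistic is reported as 0
#' (identical vectors) or infinite, with a warning.
#'
#' @param x,y Equal-length paired samples (n >= 2).
#' @return One-row tibble: `t_stat`, `p_value`, `df`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("Need at least two pairs.")
  d <- x - y
  if (sd(d) == 0) {
    warn("Zero-variance differences; paired t-test is degenerate.")
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble(t_stat = t_stat,
                  p_value = if (t_stat == 0) 1 else 0,
                  df = length(x) - 1))
  }
  ht <- t.test(x, y, paired = TRUE)
  tibble(t_stat = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter))
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors, n >= 3, each with nonzero
#'   variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least three observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in `x` or `y`.")
  cor(x, y)
}

#' Intraclass correlation for method agreement
#'
#' Single-measures ICC from the two-way subjects x raters mean-squares
#' decomposition. The default `"agreement"` form is the two-way
#' random-effects absolute-agreement ICC(2,1), which penalises a constant
#' offset between methods (a device can correlate perfectly with the
#' criterion yet agree poorly); `"consistency"` gives ICC(3,1), which does
#' not.
#'
#' @param m Numeric matrix with one row per subject and one column per
#'   rater/method (n >= 3 rows, k >= 2 columns).
#' @param form `"agreement"` (default) or `"consistency"`.
#' @return The ICC. If every value is identical the decomposition is
#'   degenerate and 1 is returned with a warning.
#' @export
#' @examples
#' icc_agreement(cbind(1:5, 1:5 + 10))  # near 0 despite r = 1
icc_agreement <- function(m, form = c("agreement", "consistency")) {
  form <- arg_match(form)
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3 || k < 2) abort("Need at least 3 subjects and 2 raters.")
  if (anyNA(m)) abort("Missing values are not supported.")
  grand <- mean(m)
  if (all(m == m[1, 1])) {
    warn("All values identical; ICC set to 1 by convention.")
    return(1)
  }
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((m - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (form == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA across two or more independent
#' groups.
#'
#' @param groups List of numeric vectors, one per group (each n >= 2).
#' @return One-row tibble: `f_stat`, `p_value`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a list of at least two samples.")
  }
  if (any(lengths(groups) < 2)) abort("Every group needs n >= 2.")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- oneway.test(values ~ g, var.equal = TRUE)
  tibble(f_stat = unname(ht$statistic), p_value = ht$p.value,
         df_between = unname(ht$parameter[1]),
         df_within = unname(ht$parameter[2]))
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' Pairwise two-sample t-tests between all group pairs with p-values
#' multiplied by the number of comparisons (capped at 1).
#'
#' @param groups Named or unnamed list of numeric vectors, one per group.
#' @return Tibble with one row per pair: `group1`, `group2`, `p_value`
#'   (unadjusted), `p_adjusted`.
#' @export
bonferroni_pairwise <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a list of at least two samples.")
  }
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  k <- ncol(pairs)
  purrr::map_dfr(seq_len(k), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    p <- t.test(groups[[i1]], groups[[i2]])$p.value
    tibble(group1 = nm[i1], group2 = nm[i2], p_value = p,
           p_adjusted = min(1, k * p))
  })
}
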