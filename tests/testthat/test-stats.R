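test_that("MAPE follows the per-observation definition", {
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mape(0.239, 0.069), 246.376811594203, tolerance = 1e-12)
  expect_equal(mape(c(2, 4), c(1, 2)), 100)
  expect_error(mape(c(1, 2), c(1, 0)), "zero")
  expect_error(mape(1:3, 1:2), "equal length")
})

test_that("summary-statistic Cohen's d reproduces the published effect sizes", {
  pub <- published_validation()
  for (i in seq_len(nrow(pub))) {
    expect_equal(
      round(cohens_d(pub$gt_m[i], pub$gt_s[i], pub$cm_m[i], pub$cm_s[i]), 2),
      pub$es[i])
  }
  expect_equal(cohens_d(5, 1, 5, 2), 0)
  expect_warning(d <- cohens_d(2, 0, 1, 0), "infinite")
  expect_equal(d, Inf)
})

test_that("published MAPE values recompute from their own group means", {
  pub <- published_validation()
  for (i in seq_len(nrow(pub))) {
    got <- round(mape(pub$gt_m[i], pub$cm_m[i]), 2)
    if (pub$mape_consistent[i]) {
      expect_equal(got, pub$mape[i])
    } else {
      # the one internally inconsistent tabulated cell: the value implied
      # by its own means is 222.52
      expect_equal(got, 222.52)
    }
  }
})

test_that("paired t matches the hand-computed small case and degenerates safely", {
  x <- c(2, 3, 4)
  res <- paired_t(x + c(1, 2, 3), x)
  expect_equal(res$t_stat, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  # cross-check p against the t distribution directly
  expect_equal(res$p_value, 2 * pt(-2 * sqrt(3), df = 2))
  expect_warning(deg <- paired_t(x, x), "degenerate")
  expect_equal(deg$t_stat, 0)
  # p shrinks as n grows at a fixed standardized difference
  set.seed(3)
  d10 <- rnorm(10, 1, 0.5)
  d40 <- c(d10, rnorm(30, 1, 0.5))
  expect_lt(paired_t(d40, rep(0, 40))$p_value,
            paired_t(d10, rep(0, 10))$p_value)
})

test_that("Pearson correlation handles exact linear relations", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 5)), "variance")
  expect_error(pearson_r(1:2, 1:2), "three")
  # permutation null is centred at zero
  set.seed(4)
  r <- replicate(300, pearson_r(x, sample(x)))
  expect_lt(abs(mean(r)), 0.1)
})

test_that("absolute-agreement ICC penalises offsets; consistency does not", {
  expect_equal(icc_agreement(cbind(1:6, 1:6)), 1)
  # constant offset: r stays 1, agreement collapses
  m <- cbind(1:6, 1:6 + 50)
  expect_lt(icc_agreement(m), 0.05)
  expect_equal(icc_agreement(m, form = "consistency"), 1)
  # strictly decreasing in the offset size
  offs <- c(0.5, 1, 2, 4, 8)
  iccs <- vapply(offs, function(o) icc_agreement(cbind(1:6, 1:6 + o)),
                 numeric(1))
  expect_true(all(diff(iccs) < 0))
  # invariant under subject permutation
  set.seed(5)
  m2 <- cbind(rnorm(8), rnorm(8))
  p <- sample(8)
  expect_equal(icc_agreement(m2), icc_agreement(m2[p, ]))
  expect_warning(one <- icc_agreement(matrix(3, 4, 2)), "identical")
  expect_equal(one, 1)
  expect_error(icc_agreement(cbind(1:2, 1:2)), "3 subjects")
})

test_that("mean-squares ICC agrees with an aov variance-decomposition oracle", {
  # independent route: mean squares from a two-way fixed-effects aov fit
  icc_via_aov <- function(m, form) {
    n <- nrow(m); k <- ncol(m)
    d <- data.frame(y = as.vector(m),
                    subj = factor(rep(seq_len(n), k)),
                    rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    if (form == "agreement") {
      (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    } else {
      (msr - mse) / (msr + (k - 1) * mse)
    }
  }
  toy <- cbind(c(9, 6, 8, 7), c(2, 1, 4, 1))
  for (form in c("agreement", "consistency")) {
    expect_equal(icc_agreement(toy, form = form), icc_via_aov(toy, form))
  }
  set.seed(6)
  for (i in 1:10) {
    m <- cbind(rnorm(7, 10, 2), rnorm(7, 11, 2))
    expect_equal(icc_agreement(m), icc_via_aov(m, "agreement"))
    expect_equal(icc_agreement(m, form = "consistency"),
                 icc_via_aov(m, "consistency"))
  }
})

test_that("one-way ANOVA and Bonferroni post-hoc follow their definitions", {
  g_same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(one_way_anova(g_same)$f_stat, 0)
  # two groups: F = t^2 from the pooled two-sample t-test
  set.seed(7)
  g1 <- rnorm(10); g2 <- rnorm(12, 0.5)
  res <- one_way_anova(list(g1, g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(res$f_stat, unname(tt$statistic)^2)
  expect_equal(res$p_value, tt$p.value)

  groups <- list(a = g1, b = g2, c = rnorm(11, 1))
  bp <- bonferroni_pairwise(groups)
  expect_equal(nrow(bp), 3)
  expect_equal(bp$p_adjusted, pmin(1, 3 * bp$p_value))
  expect_true(all(bp$p_adjusted >= bp$p_value))
  expect_error(one_way_anova(list(1:3)), "two samples")
  expect_error(one_way_anova(list(1:3, 5)), "n >= 2")
})

test_that("agreement tables score a method per cell and pooled per group", {
  specs <- default_group_specs()
  roster <- simulate_cohort(specs, n_per_group = 4, seed = 8)
  epochs <- simulate_trials(roster, specs, noise_scale = 0.5, seed = 8)
  est <- estimate_ee(process_epochs(epochs, roster), roster)

  ag <- agreement_table(est, model = "gt9x")
  expect_s3_class(ag, "ee_agreement")
  expect_equal(nrow(ag), 4 * 6)  # 5 speeds + pooled, per group
  cells <- dplyr::filter(ag, speed != "pooled")
  pooled <- dplyr::filter(ag, speed == "pooled")
  expect_true(all(is.na(cells$icc)) && all(!is.na(cells$es)))
  expect_true(all(!is.na(pooled$icc)) && all(!is.na(pooled$pearson_r)))
  expect_true(all(cells$mape_pct >= 0))

  # a method scored against itself is perfect
  self <- est
  self$self_ee_kcal_kg_min <- self$cm_ee_kcal_kg_min
  ags <- suppressWarnings(agreement_table(self, model = "self"))
  expect_true(all(ags$mape_pct == 0))
  sp <- dplyr::filter(ags, speed == "pooled")
  expect_equal(sp$icc, rep(1, 4))
  expect_equal(sp$pearson_r, rep(1, 4))

  # dropping one speed only removes that cell's rows
  est2 <- dplyr::filter(est, speed_kmh != 8.0)
  ag2 <- agreement_table(est2, model = "gt9x")
  expect_equal(nrow(ag2), 4 * 5)
  expect_false("8" %in% ag2$speed)
  expect_error(agreement_table(est, model = "nope"), "not found")
})
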