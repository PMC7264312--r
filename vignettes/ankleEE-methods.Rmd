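---
title: "Estimating and validating energy expenditure from ankle-worn accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and validating energy expenditure from ankle-worn accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Count-based energy-expenditure (EE) prediction equations for accelerometers
are calibrated for a particular wearing site, usually the hip or wrist. The
widely used Freedson VM3 combination equation,

$$\mathrm{EE}\ (\mathrm{kcal/min}) = 0.001064\,\mathrm{VM}
  + 0.087512\,\mathrm{BW} - 5.500229,$$

predicts EE from the vector magnitude of the triaxial counts per minute
(VM) and body weight (BW, kg). The ankle experiences far larger impact
accelerations than the hip during walking and running, so an ankle-worn
device feeds much larger VM values into a waist-calibrated equation and
overestimates EE severely — by roughly a factor of three in the cohort this
package emulates — while still tracking workload (high correlation with the
criterion, very low absolute agreement). ankleEE implements the full
analysis used to quantify that failure and to re-calibrate the equation for
the ankle, for four fitness groups: sedentary (SG), exercise-habit (EHG),
non-endurance athletes (NEG) and endurance athletes (EG).

## The measurement model

**Criterion EE.** Breath-by-breath gas exchange aggregated to 10-s epochs
gives oxygen uptake and carbon-dioxide output in L/min. Total EE follows
the abbreviated Weir equation
$\mathrm{EE} = 3.491\,\dot VO_2 + 1.106\,\dot VCO_2$ (kcal/min)
(`weir_ee()`). The participant's resting metabolic rate (RMR, kcal/day) is
subtracted after conversion to kcal/min with 1440 min/day (`activity_ee()`;
the daily-to-minute conversion is the only dimensionally consistent reading
of subtracting a resting rate from a per-minute total), and the result is
divided by body weight (`normalize_by_bw()`), giving activity-related EE in
kcal/kg/min.

**RMR.** The RMR prediction equation is a pluggable strategy
(`rmr_kcal_day()`), defaulting to the revised Harris–Benedict equations;
Mifflin–St Jeor and a constant stub are also provided. Predicted RMR at the
groups' mean anthropometrics lands within about 10% of the groups'
bioimpedance-measured values, which is as close as two unrelated RMR
methods can be expected to agree; the tests assert a 25% sanity band.

**Device EE.** Per epoch, $\mathrm{VM} = \sqrt{a_1^2 + a_2^2 + a_3^2}$
(`compute_vm()`); VM is computed per epoch and then averaged, matching how
epoch-logging firmware integrates counts, and converted to the
counts-per-minute scale of the prediction equations by the factor
$60/\text{epoch length}$ (`vm_to_per_minute()`). The per-minute convention
is pinned by dimensional analysis: the corrected ankle models' VM
coefficients (about $6\times10^{-6}$ per count·min⁻¹ on a response of
~0.1–0.2 kcal/kg/min) are only consistent with VM in the tens of thousands,
i.e. per-minute ankle counts at running speeds.

**Steady state.** Each treadmill stage (4.8, 6.4, 8.0, 9.7, 11.3 km/h, at
least 3 min) includes a metabolic transient. `trim_steady_state()` deletes
the first 120 s of every stage and the last 10 s (guarding against clock
misalignment between devices), and requires at least 30 s of survivors —
the bound is inclusive, so a 160-s stage (exactly 30 s surviving) is kept.
Epochs are half-open intervals aligned to the epoch grid; misaligned input
is an error rather than silently resampled. Resting HR is the minimum over
the final 5 min of a 20-min seated rest (`resting_hr()`), the stage
heart-rate reserve is $\mathrm{HRR} = \mathrm{HR}_{max} -
\mathrm{HR}_{rest}$ over the steady window (`stage_hrr()`), and any stage
in which HR exceeds $220 - \text{age}$ is excluded (`exceeds_safety()`).

## Calibration models

Two ankle-specific corrections are fitted per group by ordinary least
squares on per-stage steady-state means (`fit_linear_ee()`):

* **Model A**: $\mathrm{EE} = \beta_0 + \beta_1 \mathrm{VM} + \beta_2
  \mathrm{BW}$
* **Model B**: $\mathrm{EE} = \beta_0 + \beta_1 \mathrm{VM} + \beta_2
  \mathrm{BW} + \beta_3 \mathrm{HRR}$

with EE in kcal/kg/min. Fitting uses a seeded random 70/30
training/validation split. The split is stratified by group × speed by
default (stratification stabilises small-sample validation; it can be
disabled with `stratify = FALSE`). Training quality is reported as $R^2$
and the standard error of estimate $\sqrt{SSE/(n-p-1)}$; held-out quality
as Pearson r and absolute-agreement ICC. Fitting on per-stage means (rather
than pooled epochs) matches the granularity at which the reference tables
report estimates; per-epoch fitting can be performed by passing epoch-level
rows to `fit_linear_ee()` directly. The published coefficient sets for both
models and all four groups ship as a versioned JSON resource
(`ee_model_coefs()`), and fitted models export to the same schema
(`write_ee_model()`), so a de-novo calibration is usable anywhere a
built-in one is. Negative predictions are preserved internally — clamping
would break the linearity that fitting and the t-statistics rely on — and
clamped to zero only in reporting (`agreement_table(clamp_negative =
TRUE)`).

## Agreement statistics

`agreement_table()` reproduces the reference validation layout: per group ×
speed it reports the paired t-test, Cohen's d and MAPE; per group, pooled
across speeds at stage level, Pearson r and the ICC.

* **Cohen's d** uses the pooled-SD equal-n form $|m_1 - m_2| /
  \sqrt{(s_1^2 + s_2^2)/2}$. This variant is pinned because it reproduces
  every published effect-size cell to two decimals from the published
  means and SDs — the strongest available anchor against formula drift.
* **MAPE** is per-observation, $\{\sum |pred - act| / act\} \times 100 / n$.
* **ICC** defaults to the two-way random-effects absolute-agreement
  single-measures form ICC(2,1), computed from the subjects × raters
  mean-squares decomposition. Absolute agreement is the scientifically
  relevant form here: the ankle-worn device correlates with the criterion
  almost perfectly yet disagrees by a large constant factor, which only an
  absolute-agreement index penalises. The consistency form ICC(3,1) is
  available via `icc_form = "consistency"`.
* **ANOVA**: group comparisons use the classical equal-variance one-way F
  test with Bonferroni-adjusted pairwise two-sample t-tests
  (`one_way_anova()`, `bonferroni_pairwise()`), two-sided, α = 0.05.

One tabulated MAPE cell in the reference validation table (EHG at
6.4 km/h) is internally inconsistent with its own group means (the means
imply 222.52, not the printed 225.52); the package's consistency tests pin
the value implied by the means. Note also that the reference table labels
Pearson r a "coefficient of determination" while reporting r-scale values;
this package reports the correlation r and does not square it.

## The synthetic treadmill-trial generator

No raw cohort data are available, so the generator
(`default_group_specs()`, `generate_cohort()`, `generate_trial()`) emulates
the study's statistical structure and makes every downstream stage testable:

* **Anthropometrics** are truncated-normal draws (mean ± 3 SD, with floors
  at 18 y, 140 cm, 35 kg) at the published group means/SDs; sex follows
  each group's published ratio; resting HR is uniform over a plausible
  group range (lower for athletes); RMR comes from the configured
  prediction equation.
* **Stage targets.** For each participant × speed the generator draws a
  criterion-EE and a device-EE target (kcal/kg/min) from the group's
  published per-speed distributions, correlated at `ee_correlation`
  (default 0.95) within the cell: both measures respond to the same
  workload, so a participant who expends more than the group mean also
  accumulates more counts. Independent draws would make the device signal
  uninformative about within-group EE differences, which no physical
  sensor is. The marginal per-speed means and SDs are unaffected by this
  correlation.
* **Signal construction inverts the analysis.** Gas channels invert the
  Weir equation at a respiratory quotient drawn uniformly in [0.85, 1.00]
  (the physiological walking-to-running range; the Weir formula needs a
  VO₂/VCO₂ split that group-level summaries do not constrain), after
  adding RMR back and un-normalising by body weight. Counts invert the
  Freedson VM3 equation at the participant's body weight and split VM over
  the axes in a fixed 2:1:2 direction (an exact-norm Pythagorean split with
  a dominant vertical axis). Heart rate is
  $\mathrm{HR}_{rest} + f \cdot (220 - \text{age} - \mathrm{HR}_{rest})$
  with per-speed reserve fractions $f$ = 0.35/0.45/0.55/0.68/0.80 (−0.05
  for the athlete groups) — stage-level HR is not published, so these are
  package defaults chosen as a plausible monotone intensity mapping, and
  they are fully configurable.
* **Transients.** The first 120 s of each stage ramp linearly from 60% to
  100% of the steady target (any shape works, since the trimmer must
  discard it — the ramp exists to catch a trimmer that does not), and the
  rest block ends with five minutes whose HR minimum is exactly the
  participant's resting HR.
* **Noise.** `noise_scale` multiplies every random component: between-
  subject target SDs, 2% epoch-level jitter on gas and counts, and 2-bpm HR
  jitter. At `noise_scale = 0` the pipeline returns the group means exactly
  (to floating point), which the round-trip tests exploit; at 1 it
  reproduces the published between-subject SDs.

What the generator does **not** emulate: raw 30 Hz waveforms, gait
biomechanics, device non-wear, count saturation, drift between devices, or
any within-participant correlation structure across speeds beyond the
shared anthropometrics. Passing tests therefore demonstrate that the
analysis chain is correct and that the published group-level structure is
reproduced — not that the corrected models would transfer to a new cohort.

## Numerical and design choices

* Epoch timestamps must align to the epoch grid; trimming counts epochs via
  `ceiling(seconds / epoch_length)`.
* The ICC of a degenerate matrix (all values identical) is defined as 1
  with a warning; zero-variance paired differences yield a flagged t of 0
  (identical vectors) or ±Inf.
* Cohort and trial generation, the 70/30 split and the design-table
  generator are all seeded; identical seeds give bit-identical outputs, and
  the RNG state of the caller is restored.
* The default simulated study uses 30 participants per group, 180-s stages,
  10-s epochs and a 1200-s rest — the reference protocol — and runs in a
  few seconds; parameter-recovery checks use n = 150 design rows over 100
  seeds.

## Known limitations

* The published corrected-model coefficients are printed with the VM term
  rounded to one significant figure, so evaluating the *printed* rows on
  synthetic data carries up to ~8% slope error; agreement conclusions about
  the corrected models should be drawn from de-novo fits, which is what
  `run_pipeline()` reports alongside the printed rows.
* Published ICCs for the corrected models cannot be reproduced exactly
  without the raw cohort; the package targets the qualitative pattern
  (near-zero ICC for the waist equation at the ankle, ICC above 0.9 after
  re-calibration).
* The criterion chain assumes the roster's RMR is the one subtracted; if a
  different RMR equation is configured between simulation and analysis the
  round-trip identity no longer holds, by design.
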