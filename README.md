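# ankleEE

Energy-expenditure (EE) estimation and validation for ankle-worn triaxial
accelerometers paired with a heart-rate monitor, benchmarked against
indirect calorimetry.

Count-based EE equations are calibrated for a wearing site. The Freedson
VM3 combination equation,

    EE (kcal/min) = 0.001064 · VM + 0.087512 · BW − 5.500229,

with VM the vector magnitude of the triaxial counts per minute and BW the
body weight (kg), was developed for the waist. The ankle takes the largest
impact accelerations during gait, so ankle-worn devices push far larger VM
values through this equation and overestimate EE by roughly 200%, while
still correlating strongly with the criterion — high validity, poor
reliability. ankleEE implements the full pipeline that quantifies this and
re-calibrates the equation for the ankle across four fitness groups
(sedentary SG, exercise-habit EHG, non-endurance athletes NEG, endurance
athletes EG):

* **Criterion EE** from breath gases via the Weir equation
  (`EE = 3.491·V̇O₂ + 1.106·V̇CO₂`, kcal/min), minus predicted resting
  metabolic rate, per kg of body weight;
* **Device EE** from epoch counts via the Freedson VM3 equation and via
  published ankle-specific corrections, Model A
  (`EE ~ VM + BW`) and Model B (`EE ~ VM + BW + HRR`, with the
  heart-rate reserve `HRR = HRmax − HRrest` as a fitness covariate);
* **Signal processing**: per-epoch vector magnitude, steady-state trimming
  (drop the first 120 s and last 10 s of each stage, require ≥ 30 s),
  resting HR, stage HRR, and the `220 − age` HR safety rule;
* **De-novo calibration**: seeded, stratified 70/30 cross-validated OLS
  fits per group, with broom-style `tidy()`/`glance()` and JSON export;
* **Agreement battery**: paired t, pooled-SD Cohen's d, MAPE, Pearson r,
  absolute-agreement ICC(2,1), one-way ANOVA with Bonferroni post-hoc;
* **A synthetic treadmill-trial generator** that reproduces the published
  group-level structure (anthropometrics; per-speed EE means/SDs at 4.8,
  6.4, 8.0, 9.7 and 11.3 km/h) so the whole pipeline runs and is tested
  without any device data.

## Worked example

```r
library(ankleEE)

specs     <- default_group_specs()                      # published cohort structure
roster    <- simulate_cohort(specs, n_per_group = 30, seed = 1)
epochs    <- simulate_trials(roster, specs, seed = 1)   # 10-s epoch streams
features  <- process_epochs(epochs, roster)             # steady-state trimming
estimates <- estimate_ee(features, roster)              # criterion + device EE

freedson <- agreement_table(estimates, model = "gt9x")
render_agreement_text(dplyr::filter(freedson, group == "SG"))
```

```
Group Speed   Actual EE (kcal/kg/min)  Pred EE (kcal/kg/min)     ES  MAPE (%)       r     ICC
---------------------------------------------------------------------------------------------
SG    4.8             0.068 ± 0.007         0.228 ± 0.043   5.24    234.16
SG    6.4             0.104 ± 0.013         0.336 ± 0.068   4.75    219.83
SG    8               0.143 ± 0.007         0.430 ± 0.075   5.35    198.15
SG    9.7             0.172 ± 0.007         0.550 ± 0.070   7.57    218.54
SG    11.3            0.195 ± 0.011         0.609 ± 0.093   6.24    210.43
SG    pooled          0.137 ± 0.047         0.431 ± 0.156           216.22   0.950   0.124
```

The waist-calibrated equation overestimates ankle EE three-fold in every
speed cell (MAPE ≈ 200–230%, effect sizes ≈ 5–8) yet tracks workload
almost perfectly (pooled r = 0.95); the absolute-agreement ICC of 0.124
exposes the systematic offset that the correlation hides. Re-calibrating
for the ankle fixes this:

```r
fit <- fit_group_models(estimates, with_hrr = FALSE, seed = 1)$SG
fit
```

```
EE calibration fit (modelA)
 EE = 0.000004 x VM -0.001524 x BW +0.118880  [kcal/kg/min]
  R^2 = 0.868, SEE = 0.0171 (n_train = 105)
  validation (n = 45): r = 0.932, ICC = 0.926
```

The de-novo Model A explains 87% of the criterion variance with a standard
error of estimate of 0.017 kcal/kg/min, and its held-out predictions agree
with calorimetry (ICC 0.93) where the uncorrected equation did not (0.12).
`run_pipeline()` chains all of the above (simulate → process → estimate →
fit → validate) and writes CSV/JSON reports; `autoplot()` methods and
`plot_ee_by_speed()` provide the matching figures; a thin command-line
wrapper with `simulate`/`process`/`estimate`/`fit`/`validate`/`report`/`run`
subcommands ships at `inst/cli/ee-pipeline.R`.

## Layout

* `R/` — generator, signal processing, EE models, calibration fitting,
  agreement statistics, pipeline orchestration
* `inst/extdata/ee_models.json` — versioned built-in coefficient sets
* `inst/cli/ee-pipeline.R` — command-line wrapper
* `vignettes/ankleEE-methods.Rmd` — the measurement model, generator
  design and statistical choices in detail
* `tests/testthat/` — unit, property and end-to-end acceptance tests
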