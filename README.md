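# procoda

Compositional analysis of 24-hour activity behaviors and academic
procrastination.

## What it is for

Time-use epidemiology asks how the daily allocation of time across sleep
(SLP), sedentary behavior (SB), light physical activity (LPA) and
moderate-to-vigorous physical activity (MVPA) relates to an outcome —
here, academic procrastination measured by the PASS questionnaire
(part-one total, 12–60, severity bands at 24/36/48). Because the four
durations always sum to 1440 min, they are compositional: procoda maps
them to isometric log-ratio (ilr) *pivot coordinates*

z_i = sqrt((D−i)/(D−i+1)) · ln( x_i / gmean(x_{i+1}, …, x_D) ),

fits y = β₀ + βᵀz + γᵀcovariates + ε by OLS (adjusting for gender, age,
residence), and reports:

* **per-behavior coefficients** — refit with each behavior leading the
  pivot; the first coordinate's β is "that behavior vs the geometric mean
  of the rest";
* **isotemporal substitution effects** — predicted outcome change when
  t minutes move from a donor behavior to a recipient behavior at a
  reference composition, with delta-method or bootstrap 95% CIs;
* **dose–response curves** — the same along a 5–60 min grid, linear or
  via penalized cubic-spline GAMs (`mgcv`, GCV-selected smoothing, with
  deviance explained);
* **PASS scoring** — totals, dimensions, expectation subscale, severity
  category and chronic-procrastination prevalence;
* **a seeded logistic-normal generator** — synthetic cohorts whose true
  substitution effects, per-part coefficients and explained variance can
  be calibrated *exactly*, for parameter-recovery studies.

## Worked example

```r
library(procoda)

cfg    <- generator_config(n = 986, seed = 1)   # defaults: see vignette
cohort <- generate_cohort(cfg)

fit <- fit_outcome_model(cohort$data)
#> Compositional outcome model (ap_total), n = 986, R^2 = 0.259

per_part_coefficient_table(cohort$data)
#>   behavior    beta ci_low ci_high  p_value
#> 1      SLP  1.3601  0.104    2.62 3.38e-02
#> 2       SB  0.0467 -1.215    1.31 9.42e-01
#> 3      LPA  2.5295  1.323    3.74 4.23e-05
#> 4     MVPA -3.9364 -5.192   -2.68 1.10e-09

substitution_effect(fit, donor = "SB", recipient = "MVPA", minutes = 15)
#>   donor recipient minutes delta ci_low ci_high method
#> 1    SB      MVPA      15 -1.07  -1.42   -0.72  delta
```

Reading: on this synthetic cohort a day with relatively more MVPA is
associated with a lower procrastination score (per-part β = −3.94, 95% CI
−5.19 to −2.68), and moving 15 min from sitting into MVPA at the cohort's
mean day predicts a 1.07-point drop (the generator's planted truth for
this seed's configuration is −1.16, inside the CI). The per-part betas of
one linear model always sum to zero — they are four views of a
three-dimensional parameter.

`run_pipeline(cfg, out_dir = "out")` chains everything (descriptives with
ANOVA/χ² group tests, model, per-part table, 12-pair substitution table,
linear and spline dose–response curves) and writes CSVs plus a JSON run
manifest; it accepts a generator config, a subject CSV, or a YAML file.

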