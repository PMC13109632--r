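# pursuitlst

Latent state–trait modeling of smooth pursuit eye movement (SPEM)
performance.

Smooth pursuit — the slow tracking of a moving target — is a workhorse
measure in individual-differences and clinical oculomotor research, where a
central question is how much of a person's score reflects a stable trait
versus the situation on the day of testing. Classical test theory folds
situational fluctuation into measurement error; latent state–trait (LST)
theory separates the two. This package implements the complete analysis
chain for repeated-measures pursuit studies:

* **Signal stage** — sinusoidal (0.4 Hz, ±9.80°) and triangular (13°/s)
  task trajectories; half-cycle segmentation; 17-sample least-squares
  differentiation; velocity/acceleration/amplitude saccade detection
  (≥ 60°/s, or ≥ 22°/s with ≥ 3800°/s², amplitude ≥ 1°); time-weighted
  velocity gain and RMSE with their intra-individual SDs; saccade
  frequency; test-set splitting; 50%-window and 4×IQR exclusion rules.
* **SEM stage** — a from-scratch FIML engine for latent state (LS),
  latent state–trait (LST, LST_T), latent growth curve (LGC) and latent
  trait (LT) models with 3 occasions × 2–4 indicators; measurement
  invariance ladder; restriction ladders with automatic negative-variance
  remedies; CFI/RMSEA/SRMR; Huber–White sandwich standard errors and
  scaled χ² (difference) tests; Mardia's normality test; model selection
  toward the most restrictive adequate model.
* **Decomposition** — for each manifest variable X_ik of the selected
  model: consistency `Con = λ²γ²Var(T)/Var(X)` (plus slope terms for LGC),
  occasion specificity `Spe = λ²Var(SR)/Var(X)`, and reliability
  `Rel = Con + Spe`, with per-variable averages and trait-share
  percentages.
* **Classical reliability** — Cronbach's α with half-cycle equalization,
  split-half Spearman, two-way mixed absolute-agreement ICC(A,1), and
  repeated-measures ANOVA with Mauchly/Greenhouse–Geisser handling and
  Bonferroni post hocs.
* **Synthetic data** — trace-level and latent-level generators with known
  ground truth (injected saccades/blinks come with an event log), so the
  whole chain is testable offline.

## Worked example

Simulate a trait-dominated pursuit variable (trait variance 4,
state-residual variance 1.6, error variance 0.08 — population consistency
4/5.68 ≈ 0.70), let the selection procedure find the best model, and
decompose its variance:

```r
library(pursuitlst)

params <- latent_sim_params(n_subjects = 500, trait_var = 4,
                            state_residual_vars = 1.6, error_vars = 0.08,
                            slope_loadings = 0, seed = 42)
sim <- simulate_latent_dataset(params)
sel <- select_model(sim$data, restarts = 2)
sel$fit
#> <lst_fit> LST_T (C), n = 500, logLik = -3827.370
#>   chi-square 16.180 on 23 df (p = 0.8475)
#>   label estimate       se
#>     eps  0.08513 0.003107
#>  var_sr  1.64446 0.075462
#>   var_t  3.69560 0.270468
#>    mu_t -0.06280 0.092282
fit_indices(sel$fit)
#> CFI 1.000 | RMSEA 0.000 (90% CI 0.000-0.021, pclose 1.000) | SRMR 0.019
average_decomposition(decompose_fit(sel$fit))
#>         rel       con       spe
#> 1 0.9843075 0.6811923 0.3031152
```

The selection lands on the most restrictive state–trait model without
occasion mean shifts (LST_T, ladder C: τ-equivalent indicators, equal state
residuals), and the decomposition recovers the simulated population: about
68% trait variance, 30% situational variance, reliability 0.98.

The signal stage works the same way from a gaze trace:

```r
tgt <- generate_target("sinusoidal")        # 0.4 Hz, +/-9.80 deg, 76.57 s
tr  <- simulate_gaze_trace(tgt, gain = 0.9, seed = 7,
         params = trace_sim_params(saccade_rate_hz = 0, blink_rate_hz = 0,
                                   noise_sd = 0, lag_ms = 0))
subset(trace_metrics(tr$trace, tgt)$metrics, set == 0)
#>    variable set        value valid_fraction
#> 1      gain   0 8.999593e+01              1
#> 2   sd_gain   0 1.482425e-11              1
#> 3      rmse   0 6.929646e-01              1
#> 4   sd_rmse   0 0.000000e+00              1
#> 5 sacc_freq   0 0.000000e+00              1
```

A trace simulated with gain 0.9 measures 89.996% — the velocity-gain
pipeline recovers the generating parameter to within the filter's
attenuation.

The whole chain (simulate → metrics → fit → decompose → classical) runs
from one YAML configuration via `run_pipeline()`, or from the shell through
the thin wrapper `inst/cli/pursuit-lst`.

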