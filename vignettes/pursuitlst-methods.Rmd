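---
title: "Methods: latent state-trait modeling of smooth pursuit performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent state-trait modeling of smooth pursuit performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pursuitlst)
```

## The problem

Smooth pursuit eye movements (SPEM) are the slow tracking movements that hold
a moving target on the fovea. Pursuit performance — velocity gain, positional
root mean square error (RMSE), and catch-up saccade frequency — is widely
used in individual-differences and clinical research, where it matters
whether a person's score reflects a stable *trait* or the *situation* on the
day of testing. Classical test theory lumps situational fluctuation into
measurement error; latent state–trait (LST) theory separates the two.

`pursuitlst` implements the full chain: extraction of pursuit metrics from
gaze recordings of sinusoidal and triangular tracking tasks, structural
equation models of the LST family estimated by full-information maximum
likelihood (FIML), and the resulting variance decomposition into
reliability, consistency (trait share) and occasion specificity (state
share), alongside classical reliability coefficients for comparison. A
synthetic-data generator with known ground truth makes every stage testable
without any recording hardware or external download.

## Signal stage

### Task geometry

Both standard tasks move a target horizontally with an amplitude of
±9.80°, starting at the center and moving rightward: a 0.4 Hz sinusoid over
76.57 s and a constant-velocity 13°/s triangular wave over 91.50 s, sampled
at 1000 Hz. Data before the first and after the last direction reversal are
discarded, which leaves exactly 60 half-cycles per task (30 rightward,
30 leftward). Indicators ("test sets") for the latent models are formed by
cyclic assignment of full cycles to k ∈ {2, 3, 4} sets; the odd–even split
(k = 2) guarantees both movement directions in each set.

### Differentiation

Velocity and acceleration come from a centered least-squares (Savitzky–Golay)
local quadratic fit over a 17-sample window. The exact kernel of the
eye-tracker vendor's "17-sample model" is not public; the least-squares
kernel was chosen because it is reproducible and polynomial-exact: a linear
ramp returns its slope to machine precision, and on the 0.4 Hz task sinusoid
the filter attenuates the analytic velocity by less than 0.005%. The 8 edge
samples on each side carry no full window and are treated as undefined.

### Saccade detection and masks

A sample is a saccade candidate when |v| ≥ 60°/s, or |v| ≥ 22°/s together
with |a| ≥ 3800°/s². Maximal candidate runs are kept as events when their
net amplitude is at least 1.0°. Events whose span intersects a blink
(invalid gap) extended by a ±100 ms margin are flagged *near-blink*; the
margin is configurable because no standard value exists.

Velocity gain is the time-weighted mean of the sample-wise ratio of eye
velocity to the *analytic* target velocity, ×100, restricted to contiguous
usable runs of ≥ 50 ms inside the central 50% (by time) of each half-cycle;
blinks, all saccades and tagged noise are excluded. Using the analytic
target derivative avoids double filtering, and the central-50% trim keeps
the ratio away from the reversal instants where target velocity crosses
zero. The intra-individual SD of gain is the time-weighted SD of the same
ratio samples. RMSE is the time-weighted root mean square of the eye–target
position difference over all half-cycle samples, excluding blinks,
near-blink saccades and noise but *not* ordinary catch-up saccades (they are
genuine tracking error); its intra-individual SD is taken across
per-half-cycle RMSE values, weighted by each half-cycle's usable time.
Saccade frequency counts accepted non-near-blink events per second of
usable time. Time weights are the per-sample durations, so irregular gaps
after exclusion are handled; at a constant sampling rate they reduce to
plain means.

Cells based on less than 50% of the possible time window are dropped, then
values outside [Q1 − 4·IQR, Q3 + 4·IQR] of their variable column; a zero
IQR disables outlier removal for that column.

## Latent models

Manifest variables X_ik (occasion i, indicator k) are modeled as
X_ik = λ_ik·S_i + ε_ik. The families differ in the structure of the states
S_i:

* **LS** — freely correlated states; used only for the measurement
  invariance ladder (configural → weak: equal loadings → strong: zero
  intercepts, free state means → strict: equal error variances), plus an
  indicator-specific method factor as a homogeneity check.
* **LST** — S_i = intercept_i + γ_i·T + SR_i with trait T and
  occasion-specific state residuals SR_i; free state intercepts allow
  occasion mean shifts.
* **LST_T** — as LST but with intercepts fixed to zero and a free trait
  mean: no occasion-level change.
* **LGC** — second-order growth curve: S_i = γ_i·T + σ_i·SL + SR_i with
  slope loadings σ = (0, 1, σ₃); σ₃ is estimated freely, with fallbacks
  (previous estimate, 2, 1.5, 1) when free estimation fails.
* **LT** — trait only (all SR variances zero); serves as the no-state
  reference model.

The restriction ladder A (equal error variances), B (+ equal state-residual
variances, trait loadings 1) and C (+ state loadings 1) is applied within
each family; each restriction is kept unless the (scaled) χ² difference test
rejects it at α = .05 *and* the CFI drops by at least 0.01 — the fit-index
override takes precedence, and every decision is written to a plain-text
trace.

### Estimation

The log-likelihood is evaluated casewise over each observation's missing
pattern (patterns are grouped and summarized by sufficient statistics, so
an evaluation costs one pass over patterns). Optimization uses a
quasi-Newton method from a moment-based start (cross-occasion covariances
initialize the trait variance, within-occasion covariances the state
residuals) plus deterministic jittered restarts; `fit_ml()` defaults to 5
starts, and the simulation studies in the test suite use 1–3 starts, which
the pilot behavior showed to be sufficient at their sample sizes.
Convergence requires the optimizer's own criterion plus a small numerical
score at the optimum.

Variances are estimated *unconstrained* rather than on a log scale: Heywood
cases must be visible, because the standard remedies — refitting with a
negative error variance fixed to 0, or fixing σ₃ to the estimate from the
less restrictive model when the slope variance goes negative — are triggered
by observing a negative estimate. Both remedies are applied automatically
during ladder reduction and logged.

The saturated model under FIML is fitted by direct maximization over a
Cholesky parameterization (closed-form moments when the data are complete),
so χ² = 2(ℓ_saturated − ℓ_model) is defined under the same likelihood. The
independence baseline (free means and variances, zero covariances)
factorizes into univariate fits. Robust corrections provide Huber–White
sandwich standard errors (observed-information bread, casewise-score meat)
and mean-corrected scaled χ² statistics with the scaling factor computed
from the normal-theory residual weight matrix and empirical fourth moments;
the fourth-moment matrix uses complete cases, which is exact for complete
data and an approximation under missingness. Scaled difference tests use
c_d = (d₀c₀ − d₁c₁)/(d₀ − d₁) and fall back to the unscaled statistic with
a warning when c_d ≤ 0 (a known pathology). Whether robust statistics are
used is decided by Mardia's test (`robust = "auto"` in the pipeline).

### Fit indices and conventions

CFI, RMSEA and SRMR follow the standard definitions; SRMR includes
standardized mean residuals because the mean structure is estimated. Points
where conventions genuinely diverge are exposed as parameters with these
defaults: RMSEA uses n = N (an N − 1 switch exists), the confidence
interval defaults to 90% (95% available, matching reports that print 95%
intervals), and the closeness-test null RMSEA is 0.05. Adequacy thresholds
for model selection are CFI ≥ 0.95, RMSEA ≤ 0.06, SRMR ≤ 0.08. Among
adequate, not-significantly-worse candidates the most restrictive model
(largest df) is selected, and an LGC survivor is preferred over LST_T only
when its slope mean or slope SD is significant (critical ratio ≥ 1.96).

### Variance decomposition

For the selected model, each manifest variable's model-implied variance is
split into consistency Con = λ²γ²Var(T)/Var(X) (plus slope variance and
trait–slope covariance terms in LGC models), occasion specificity
Spe = λ²Var(SR)/Var(X), and reliability Rel = Con + Spe; the identity is
exact by construction because Var(X) is model-implied. Summaries average
all indicator-occasion cells with equal weights (unrounded values are
averaged; rounding to 2 decimals / integer percent happens only at the
reporting layer), and the trait share is 100·Con/Rel.

## The synthetic-data generator

Two levels are generated. The **latent-level** generator draws trait (and
slope) scores, state residuals and errors from the model equations and
applies missingness completely at random; its defaults and the populations
used throughout the tests mirror a trait-dominated pursuit measure:
trait variance 4, state-residual variance 1.6 and error variance 0.08 give
population consistency 4/5.68 ≈ 0.70 and specificity ≈ 0.28, the
mid-range of what the decomposition reports for pursuit variables. The
trait-change population adds a slope with mean 1 (half a trait SD) and
variance 1, so both a mean change and individual differences in change are
present — the condition under which a growth-curve family is the correct
selection.

The **trace-level** generator produces eye(t) = g·target(t − lag) +
saccadic steps + noise. Injected saccades are minimum-jerk position steps
(≥ ~1.1°, duration 20 + 5·amplitude ms), which exceed the detection
criteria without modeling ocular dynamics; their signs alternate toward
zero cumulative offset so the eye does not drift away, which leaves
between-saccade velocity — and therefore gain — untouched. Blinks are
invalid gaps flanked by 50 ms artifact deflections so the near-blink logic
is exercised. The default tracking lag is 10 ms (predictive pursuit of
periodic targets shows only small phase lags; a large lag would bias the
velocity-ratio gain of a sinusoid by cos(ωΔt)). A single global seed fans
out deterministically per subject × occasion × task, so any single trace
can be regenerated in isolation.

What the generator does *not* emulate: pupil signals, vertical dynamics,
saccadic main-sequence realism beyond threshold detectability, anticipatory
or square-wave-jerk behavior, and smooth gain drifts within a recording.
Passing tests therefore demonstrate the correctness of the analysis chain
under the stated model, not robustness to every artifact of real
recordings.

## Problem sizes used in the test suite

The acceptance-style tests run: parameter recovery with 200 replicates at
n = 500; model-selection recovery with 20 replicates per scenario at
n = 500; invariance-ladder recovery and power with 15 replicates per
scenario at n = 500 (loading violation 1.5× at occasion 3); Mardia and
Mauchly type-I simulations with 200 replicates (n = 300 × 4 variables and
n = 50 × 3 occasions respectively); and signal-stage checks on full-length
1000 Hz traces. The pipeline example runs 40 subjects at a reduced 100 Hz
sampling rate, which leaves all segment-duration thresholds exactly
representable.

## Known limitations

* The scaled-statistic machinery estimates fourth moments from complete
  cases; under heavy non-MCAR missingness the scaling factor is only
  approximate.
* The exact vendor differentiation kernel is unknown; any kernel that is
  exact for quadratics will agree closely, but small numerical differences
  from other implementations are expected.
* Published robust RMSEA values scale the classic formula by the (data-set
  specific) correction factor; from printed statistics alone that factor is
  unrecoverable, so this package reports the classic formula plus the
  scaling factor separately.
* With three occasions the unrestricted LST covariance structure is
  saturated at the state level; family differences only emerge along the
  restriction ladders, which is why the selection procedure reduces
  families before comparing them.
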