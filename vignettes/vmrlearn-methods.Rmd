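---
title: "Models and methods behind vmrlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vmrlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmrlearn)
```

`vmrlearn` packages one complete individual-differences analysis of motor
adaptation under reinforcement: simulate the task and the EEG with known
ground truth, extract the sensorimotor and fronto-central EEG features,
compute the behavioral learning and retention indices, and run the
selection-then-inference statistical chain. This vignette explains the
models, the parameter choices and their rationale, the numerical
decisions, and what the validation does and does not establish.

## The task and the behavioral model

A session has 550 reaching trials toward a target 8 cm away: baseline
(1–100), adaptation (101–300) with a 30° counterclockwise cursor rotation,
no-vision (301–500) with all visual feedback removed, and washout
(501–550). Reach direction θ(n) is the signed angle between hand and
target where the hand crosses the 8 cm circle, with clockwise compensation
positive, so full compensation of the rotation reads +30°.

The simulator drives θ with the simplest model that reproduces the
rise-and-decay shape of adaptation data, a single-state error-driven
learner:

* feedback trials: `u[n+1] = a·u[n] + B·(target − θ[n])`, with
  `θ[n] = u[n] + ε[n]`, `ε ~ N(0, σ_m²)` execution noise; `target` is
  +30° during adaptation and 0 elsewhere;
* no-vision trials: `u[n+1] = r_nv · u[n]` — pure geometric decay, which
  is what the retention index measures.

Defaults: `a = 0.99`, learning gain `B = 0.12`, motor noise
`σ_m = 3.5°` (a typical between-trial reach SD), no-vision retention
`r_nv = 0.99`. The steady-state compensation fraction is
`B/(1 − a + B)`, and the expected retention fraction across the 200
no-vision trials is `(1 − r^200)/(200(1 − r))`; the cohort generator
inverts these maps (the latter numerically with `uniroot`) to translate
per-participant learning and retention targets into `(B, r_nv)`.

Scoring follows the published incentive scheme exactly: reward trials earn
4/3/2/1/0 points for a hit or errors below 10°, 20°, 30°, or at least
30°; punishment trials lose 0/−1/−2/−3/−4 on the mirrored scale;
"Slow" (max speed < 312 mm/s) or "Fast" (> 469 mm/s) movements count as
the worst bin in either condition. The reward group accumulates from 0 and
the punishment group spends down an 800-point endowment; the running total
is clipped to [0, 800]. A "hit" is operationalized angularly as an
endpoint error within 1.8°, from the geometry of a 0.5 cm target at 8 cm
(`atan(0.25/8)`); the original task description never states an angular
hit criterion, so this is configurable. Movement speed is drawn from a
normal truncated between the two thresholds — slow/fast labels are
nuisance events and appear only if injected explicitly.

Success/failure labels for the feedback ERP contrast mark only the best
possible outcome as success (4 points under reward, 0 under punishment);
everything else is a failure.

## Behavioral indices

Learning amount is the mean θ over late adaptation (201–300) divided by
30°, in percent; retention amount is the mean θ over the full no-vision
block (301–500) on the same scale. The early/late split of each block into
halves (101–200/201–300 and 301–400/401–500) defines the four phases for
the mixed ANOVA and the early/late EEG features; only the late-adaptation
and no-vision ranges are externally fixed, so symmetric halving is the
natural completion. Phase means skip missing trials rather than imputing,
and include "Slow"/"Fast" trials (whether the original analysis excluded
them is unstated; exclusion is a one-line filter upstream).

## The synthetic EEG generator

The generator's job is to make fixtures whose ERD and FRN the extractors
can be *proven* to recover, while keeping the statistical structure of
real epochs (band-limited rhythms over the correct scalp cluster, a 1/f
background everywhere, outcome-locked evoked components).

**Go-cue epochs** (−3 to +4 s) carry band-limited rhythms on the
C3-centered cluster: one sinusoidal component per integer frequency in
6–13 Hz and 15–32 Hz — slightly wider than the 8–13/15–30 Hz analysis
bands, so every analysed frequency bin holds rhythm power and the ERD
ratio is defined across the whole band mask — plus a stationary 14 Hz
component between the bands. ERD is planted by scaling the rhythm
amplitude by `sqrt(1 − ERD/100)` from 0.9 s before the go cue until 1.5 s
after it (preparatory desynchronization persisting through movement),
with 0.1 s raised-cosine ramps to limit spectral splatter. Two details
matter for exact recovery:

* *Leakage cancellation.* A 1-s Hanning window leaks each component into
  its ±1 Hz neighbours, and the interference between components at
  different frequencies oscillates with window position. The carrier
  therefore cycles through eight 1/8-s time shifts across trials; every
  interference term between components 1–7 Hz apart carries a factor
  `exp(i2π·Δf·shift)` and cancels exactly in the trial-averaged power.
  Fixtures are cleanest with a multiple of 8 trials.
* *Peak anchoring.* The suppression depth tapers by 0.5 percentage
  points per Hz away from the rhythm's center frequency (10 Hz alpha,
  22 Hz beta by default), so the extractor's argmax lands at the center
  bin rather than drifting on numerical ripple toward a band edge, where
  the ±2 Hz averaging neighbourhood would mix in the other band. The
  stationary 14 Hz buffer keeps either band's modulation out of the bins
  the other band's mask analyses.

With these choices the full extraction chain returns planted ERD within
about 1.5 percentage points at 0, 50 and 80 % — the residual error is the
known small contamination of reference-window estimates whose 1-s support
reaches past −1 s into the suppression onset, plus the taper.

**Feedback epochs** (−0.2 to +0.6 s) give all trials at the FCz-centered
cluster a common evoked wave; success trials additionally receive a smooth
Gaussian-shaped component (peak 275 ms, SD 40 ms) normalized so the
success-minus-failure difference wave has exactly the planted mean in the
200–350 ms window and negligible energy before feedback onset. Noiseless
recovery through the full chain (0.1–30 Hz filter, mastoid reference,
cluster average, baseline correction, difference wave, windowed mean) is
within 0.03 µV.

A strictly noiseless go-cue fixture would have zero reference power at
frequencies outside the planted combs, where the ERD ratio is undefined
(the map constructor rejects it); "noiseless" validation therefore uses a
0.05 µV 1/f floor, 46 dB below the rhythms, which shifts recovered ERD by
under 0.1 point.

What the generator does **not** emulate: eye/muscle artifacts and their
removal (ICA and manual rejection are deliberately out of scope), volume
conduction from a head model, bad channels and spatial interpolation, or
trial-to-trial amplitude variability of the rhythms. Passing round-trip
tests therefore demonstrates that the *estimators* are correct and
unbiased at realistic SNR, not that they are robust to artifactual real
recordings.

## Spectral and ERP feature extraction

The ERD chain is: 4th-order Butterworth band-pass 1–60 Hz (implemented as
a high-pass/low-pass cascade with mirror padding before zero-phase
`filtfilt`; padding matters — unpadded edge transients bias short-epoch
features), common-average reference, sample-wise average over the
7-channel C3 cluster, sliding-window power (1 s Hanning taper, 0.1 s
steps, one-sided periodogram scaling, trial-averaged; windows whose
support exceeds the epoch are dropped, not padded), then
`ERD(f,t) = (R(f) − A(f,t))/R(f)·100` with `R(f)` the mean power over
window centers in −2…−1 s. Power is averaged across trials *before* the
ratio (the classic convention; the suite asserts this order and that it
differs from ratio-then-average). The per-band feature is the map maximum
inside the band × the −1…0 s preparatory window — ties resolve to the
first cell in column-major order — averaged over ±0.2 s × ±2 Hz around
the peak, truncated at the map edges.

The FRN chain is: band-pass 0.1–30 Hz, linked-mastoid reference, FCz
cluster average, per-trial baseline correction over −200…0 ms, class-wise
trial means, difference wave (success − failure), and the mean over
200–350 ms (endpoints inclusive). Group-level outliers beyond ±2 sample
SDs of the mean (single pass, no iteration, pooled across conditions,
separately per phase) are flagged and set missing. Note a single extreme
value in a sample of five can never exceed 2 sample SDs — the largest
attainable |z| is `(n−1)/√n` — so meaningful exclusion needs the cohort
scale at which it is applied.

## The statistical chain

* **Mixed ANOVA** (`mixed_anova`): one within factor (phase), one between
  factor (condition). Between-subjects and within-subject strata are
  decomposed by projection (per-participant centering, then sequential
  within-stratum fits), which reproduces `aov()`'s sums of squares to
  machine precision, including unbalanced groups; participants missing a
  level are dropped listwise with a message. Mauchly's W is computed from
  the within-group-pooled covariance projected on an orthonormal contrast
  basis, with the Box chi-square approximation; Greenhouse–Geisser
  epsilon is `(Σλ)²/((k−1)Σλ²)` over the eigenvalues of that matrix
  (exactly 1 for two levels, floored at `1/(k−1)`). By default the GG
  correction multiplies both within-effect dfs by epsilon when Mauchly
  rejects at 0.05 and the factor has more than two levels.
* **Post hocs**: between-group pooled-variance t tests at each within
  level, Holm-adjusted (`stats::p.adjust`).
* **Lasso** (`lasso_fit`/`cv_lasso_1se`): objective
  `(1/2n)‖y − Xβ‖² + λ‖β‖₁`, cyclic coordinate descent with
  covariance-form updates plus an active-set refinement that solves the
  fixed-sign stationarity system exactly and verifies the KKT conditions
  (tolerance 1e-8; matches `glmnet` to ~1e-10, and reduces to analytic
  soft-thresholding on orthonormal designs). Predictors are z-scored and
  the outcome centered inside `cv_lasso_1se`; the grid is 100 log-spaced
  penalties from `λ_max = max|Xᵀy|/n` down to `10⁻³λ_max`; folds are
  seeded, redrawn (with a message) if an outcome is constant within a
  fold, and the 1SE rule takes the largest λ whose CV error is within one
  *fold-level* standard error of the minimum — the textbook convention;
  `cv.glmnet` uses a per-observation SE and is slightly more
  conservative on pure noise.
* **Final OLS** (`ols_final`): the selected columns are refit
  unstandardized so coefficients carry the outcome's units (retention %
  per raw ERD % × condition); an empty selection yields the intercept-only
  null model with adjusted R² = 0.
* **Power** (`power_regression_n`): power of the overall F test with
  noncentrality `f²·N` and dfs `(p, N−p−1)`, scanned upward for the
  smallest N reaching the target; `f2_from_r2` is `R²/(1−R²)`. With 7
  regressors, `f² = 0.33`, α = 0.05 and power 0.80 this gives N = 51.

The regression design intentionally has 13 columns (condition + six EEG
features + six interactions) even though the planning power analysis
assumed 7 regressors; both facts are reproduced as stated.

## Cohort generator calibration

Population values were fixed once, before any recovery experiment, at
magnitudes a motor-EEG practitioner would call typical: alpha ERD targets
N(45, 15²) early and N(55, 15²) late; beta ERD N(35, 12²)/N(45, 12²); FRN
N(−4, 1.5²) early attenuating to N(−2.5, 1.5²) late; learning targets
N(85, 8²) %. The planted retention model is
`retention % = 35.7 + 0.34·(late alpha ERD)·[condition = reward] + e`,
using the reported coefficients, with `e ~ N(0, 15²)` chosen so the
planted interaction explains roughly 30 % of retention variance in a
64-participant cohort — the strength of the reported final model.
Measured features add N(0, 2²) ERD-points and N(0, 0.5²) µV of
measurement noise, matched to the extractors' error on noisy fixtures.
Targets are clamped to physical ranges (ERD 2–95 %, retention 2–98 %),
and retention cannot exceed the learned state — a ceiling that visibly
attenuates very strong planted slopes.

A consequence the validation suite quantifies honestly: at exactly this
effect strength the 5-fold/1SE selection step finds the planted
interaction in only about 70 % of seeded replicates (failures are empty
selections, or a collinear sibling — all interaction columns share the
condition mask and correlate around 0.9). With a modestly stronger signal
(slope 0.5, or residual SD 10) selection is essentially certain, which the
strong-effect property test asserts. The practical reading: a single-shot
1SE selection at this SNR carries real selection uncertainty, and the
chain's null control (planted slope 0) selects the interaction in none of
the replicates.

## Problem sizes in the validation suite

The suite and the acceptance script run everything at reduced but fully
representative sizes, chosen as the package's own validation design:
EEG fixtures at 250 Hz with 8–16 go-cue epochs and 16–24 feedback epochs
per phase, pipeline smoke cohorts of 2–3 participants per group, and
feature-level recovery cohorts at the full study size (32 per group, 20
seeded replicates). Sampling rate enters nothing but the Nyquist limit
and bin spacing; all windows are defined in seconds and all bands in Hz.

## Known limitations

* The behavioral learner is single-state; it cannot express fast/slow
  two-state phenomena (spontaneous recovery, savings), and washout trials
  are emitted but not analysed.
* ERD recovery guarantees hold for the comb-structured synthetic rhythms;
  real broadband rhythms estimated from few trials carry estimator
  variance the round-trip tolerances do not cover.
* Cross-band leakage is controlled at the generator's band boundary
  buffer; center frequencies placed within 2 Hz of a band edge would
  degrade recovery.
* The Mauchly p-value uses the first-order Box chi-square approximation
  (`stats::mauchly.test` adds a higher-order series term; W agrees to
  machine precision).
* Outlier exclusion pools both feedback conditions ("group mean" is read
  as the whole cohort); a per-condition variant is a one-argument change
  upstream of the flagging call.
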