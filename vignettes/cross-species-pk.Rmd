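---
title: "Methods: cross-species estetrol exposure analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species estetrol exposure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspk)
```

# The problem

Estetrol (E4) is a natural estrogen with a terminal half-life of roughly a
day in women but only about two hours in mice. A mouse experiment meant to
mimic a human once-daily oral regimen therefore cannot simply reuse the
human dose, nor even the body-surface-area-scaled equivalent dose: the
shape of the exposure matters as much as its magnitude. `crosspk`
implements the quantitative machinery for this comparison — per-route
non-compartmental analysis (NCA), a simulator for each administration
route, and the allometric translation layer — so the whole chain from raw
concentration–time tables to the headline interspecies ratios is
reproducible and testable.

# Data model and units

A `pk_profile` holds one subject's or animal's measurements for one
administration: strictly increasing times, concentrations, a censoring
flag, the assay's lower limit of quantification (LLOQ), and dose metadata.
Units are fixed internally: **hours** for time (minutes converted on
input), **ng/mL** for concentration, **ng** for dose amounts. Rates are
kept per-hour internally and converted to per-minute with the exact factor
1/60 where the mouse i.v. convention calls for it. AUCs are reported in
h·ng/mL throughout.

Duplicate microsampling is represented as separate replicate-tagged
profiles; `average_replicates()` collapses them by the per-time arithmetic
mean of the uncensored values (a point censored in every replicate stays
censored). The time-grid alignment tolerance is one minute — tight enough
to catch misaligned designs, loose enough for clock jitter in recorded
sampling times. Averaging is idempotent by construction.

**Censoring.** The default rule is the standard NCA convention: censored
points before the first quantifiable concentration are set to zero (the
analyte genuinely starts near zero), and censored points at or after the
last quantifiable one are excluded from the terminal fit and the AUC. An
alternative LLOQ/2 imputation is selectable (`censor_blq(rule =
"half-lloq")`); the source data's own rule is not stated, so the choice is
documented rather than hidden.

**Summary statistics.** `pk_summary()` reports mean, SD, median, maximum,
geometric mean `exp(mean(ln x))` and geometric CV
`100·sqrt(exp(var(ln x)) − 1)` with the n−1 variance estimator. Some
printed geometric CVs in the source tables (e.g. 1.43% for a group whose
arithmetic CV is ~23%) are inconsistent with this standard formula; the
package makes no attempt to reproduce those cells.

# Non-compartmental analysis

- **AUC** uses the linear-up/log-down trapezoid by default: the log
  trapezoid `(C1 − C2)·Δt/ln(C1/C2)` on strictly decreasing positive
  segments (exact for exponential decay), linear elsewhere, with a linear
  fallback on any segment touching zero. A pure-linear method is available
  for comparison; the linear rule always bounds the log rule from above on
  convex decaying segments.
- **Terminal slope (λz)** is OLS of ln C on t over the last *n* points
  strictly after tmax, with *n* chosen in 3..8 by maximising the adjusted
  r²; ties (within 1e−9) go to the larger window, i.e. the longer
  apparent terminal phase. A non-negative best slope raises a
  no-terminal-phase error (a constant profile is the documented edge
  case). `t½ = ln 2/λz` in the rate's own unit.
- **Extrapolation**: `AUC(0–∞) = AUC(0–t) + C_last/λz`, with the
  extrapolated fraction reported so downstream users can flag
  poorly-sampled tails.
- **i.v. stripping** (`strip_iv()`) is the classical method of residuals:
  fit the terminal phase (→ B, β), subtract the back-extrapolated terminal
  curve from the earlier points, and fit the log residuals (→ A, α), with
  `C0 = A + B`. The residual fit uses only *distribution-dominant* points
  (residual larger than the terminal component at that time): the log of a
  residual r computed from a concentration C amplifies multiplicative
  assay noise by the factor C/r, so late near-cancelling residuals would
  dominate the variance of α and hence of C0. If fewer than two points
  pass the filter, any residual above numerical noise (10⁻⁸ of the
  measured value) is used; if that also fails, or the residual phase is
  not steeper than β, the fit degrades to a monoexponential (A = 0) with
  a warning.
- **Volume and clearance.** The reported i.v. parameter set for this
  compound is internally consistent only under the `CL = Vd·Ke`
  convention (1.80 L × 0.0058 min⁻¹ = 10.44 mL/min); the same table's
  dose and AUC give `Dose/AUC ≈ 1.65 mL/min`, and neither `Dose/C0`
  (~25 mL) nor `Dose/(AUC·Ke)` (~285 mL) reproduces the printed 1.80 L.
  The volume definition behind that value is therefore unrecoverable from
  first principles. `iv_derived_params()` consequently reports **both**
  clearance conventions and both volume estimates, and accepts an
  externally determined Vd for the `Vd·Ke` convention rather than forcing
  agreement.

# The synthetic-data generator

Every route is simulated in closed form — no ODE integration — so each
simulator can be checked exactly against its defining expression, and the
superposition simulator against a brute-force shifted-sum oracle.

**Calibration is fixed, not tunable.** Each scenario's parameters are
solved once from the study's reported anchors and are not adjusted
thereafter:

- `mouse_iv`: `calibrate_iv()` solves the 2×2 linear system `A + B = C0`,
  `A/Kd + B/Ke = AUC(0–∞)` with the reported C0 = 294.40 ng/mL,
  Kd = 0.12 min⁻¹, Ke = 0.0058 min⁻¹, AUC = 75.57 h·ng/mL, giving
  A ≈ 281.7 and B ≈ 12.7 ng/mL. Infeasible constraint sets (AUC outside
  [C0/Kd, C0/Ke]) raise a calibration error with the feasible range in
  the message.
- `mouse_sc` / `mouse_ip`: one-compartment Bateman absorption. The
  elimination rate 2.4 h⁻¹ and the absorption rate solved from
  `tmax = ln(ka/ke)/(ka − ke) = 10 min` jointly place the concentration
  45 min post-dose at ~30% of Cmax, matching the observed sharp peak-decay
  shape; the volume is then set so Cmax is exactly 90.92 (s.c.) or 70.54
  (i.p.) ng/mL. A single Bateman compartment cannot *also* match the
  reported AUC(0–∞) of 97.42 h·ng/mL — the real profile is multiphasic —
  so the fixtures prioritise the peak structure (which the structural
  acceptance checks exercise) and the fixture AUC (~56 h·ng/mL) is a
  known, documented departure.
- `mouse_oral`: two lagged depots with the same disposition as s.c.,
  absorption rate solved for a 15-min Bateman peak, second-depot lag
  0.8 h, fractions 0.20/0.13. This puts local maxima at 15 and 60 min on
  a fine grid and fixes total bioavailability at 0.33 of the s.c.
  reference, so the dose-normalised AUC ratio reproduces the observed
  ~33% oral bioavailability by construction.
- `human_single_*`: a fast primary depot (ka = 12 h⁻¹, giving tmax ≈
  30 min) plus a slow delayed depot (ka = 0.5 h⁻¹, lag 4 h) standing in
  for secondary reabsorption — it produces the observed
  decline-then-rise before the monoexponential terminal phase. Each dose
  level uses its own reported terminal half-life (28.21/19.22/26.64 h)
  and apparent volume solved from its reported AUC(0–∞)
  (38.27/90.09/321.05 h·ng/mL). Because the disposition is
  one-compartment, the simulated single-dose Cmax is *not* calibrated to
  the reported values (20.12 ng/mL at 15 mg would require a multiphasic
  disposition); exposure and terminal behaviour take priority.
- `human_multi_15mg`: the same shape with the mean half-life 24.69 h and
  volume solved from the steady-state AUC(0–24 h) = 76.79 h·ng/mL, dosed
  once daily for 14 days by superposition. The single- and multiple-dose
  anchors are deliberately calibrated independently (the reported 90.09
  vs 76.79 h·ng/mL pair is not jointly consistent with pure linear
  accumulation).
- `minipump_*`: zero-order release `Css = R0/CL` with clearance solved
  once from the 0.3 mg/kg/day anchor (Cav = 6.49 ng/mL for a 25 g mouse,
  giving CL ≈ 0.80 mL/min); 0.1 and 1 mg/kg/day follow by dose linearity.
  The onset rate uses the ~2 h mouse half-life, so the plateau is reached
  well before the first (24 h) sample.

**Noise model.** Multiplicative log-normal: each replicate is
`C_true · exp(ε)`, `ε ~ N(0, σ_ln²)`, independent per point and replicate,
with censoring applied *after* noise. Log-normal noise keeps
concentrations positive and makes the CV magnitude-independent, matching
the roughly constant relative SDs across the reported tables. Per-scenario
defaults are calibrated to those SDs: σ_ln = 0.23 for acute mouse routes
(arithmetic CV 20.83/90.92 ≈ 23% at the s.c. Cmax), 0.42 for minipumps,
0.5 for human oral. Seeds are explicit everywhere; `add_noise()` restores
the caller's RNG state.

**What the generator does not emulate:** between-animal parameter
variability (noise is residual-only), a mechanistic enterohepatic cycle
(the reabsorption depot is a phenomenological proxy), multiphasic
disposition after extravascular dosing, assay drift, or sampling-time
error. Passing tests therefore demonstrate correctness of the estimation
machinery under the stated error model, not robustness to every feature of
real data.

# Allometric translation

Dose translation uses the fixed body-surface-area Km-factor convention
(human adult 37, mouse 3; rat/rabbit/dog factors included for
extensibility): `MED = dose_human(mg/kg) × 37/3`. The human reference
weight is 60 kg — the value uniquely consistent with the 15 mg → 0.25 mg/kg
row of the dose-translation table — and configurable. Display rounding
(mg/kg to 2 decimals, MED and fold-ratios to integers, mirroring the
headline "12×", "2×", "10×" figures) is kept separate from the
full-precision values, which are always returned alongside.

Two conventions exist for the empirical dose-correction factor: the study
compares its predicted MED (3 mg/kg/day) with the *tested* minipump dose
whose exposure brackets the human value (0.3 mg/kg/day → 10-fold), even
though that dose over-exposes by ~1.9×; interpolating the tested doses to
exact exposure match instead gives ~0.16 mg/kg/day and a ~19-fold
correction. Both are computable (`empirical_dose_correction()` with either
matched dose); the package takes no position on which is "correct".

Dose proportionality (`dose_proportionality()`) is ordinary least squares
of Cav on dose rate with r² computed as the squared Pearson correlation; a
zero-variance response is reported as r² = 0 rather than NaN.

# Numerical choices and problem sizes

- Trapezoid endpoints interior to a sampling interval are linearly
  interpolated.
- λz window: 3..8 points, adjusted r², tie tolerance 1e−9 toward more
  points; the tmax point itself is always excluded.
- `calibrate_iv()` treats |A| or |B| below 1e−9 as zero (the
  monoexponential limit `AUC = C0/Ke` is exact).
- The Bateman `ka = ke` degeneracy switches to the limiting form
  `ka·t·e^(−ka·t)` within a relative tolerance of 1e−10.
- File I/O prints doubles with 17 significant digits so write→read→write
  round-trips are byte-identical, and result tables are byte-stable across
  runs under a fixed seed.
- Problem sizes: the steady-state human curve is evaluated on a 0.1 h grid
  over 14 days (3361 points); oracle comparisons use 0.01 h grids; the
  parameter-recovery study uses 200 simulated datasets of 11 time points ×
  2 replicates at σ_ln = 0.1, which completes in well under a minute.

# Known limitations

- Single-route, single-analyte NCA: no population-PK or mixed-effects
  estimation, and no compartmental fitting beyond the two-phase i.v.
  stripping.
- The extravascular fixtures trade AUC fidelity for peak-shape fidelity
  (see above); bioavailability comparisons between *simulated* routes are
  meaningful by construction only for oral-vs-s.c.
- The allometric layer implements the fixed Km-factor method only — no
  multi-species regression on log body weight.
- Geometric CVs follow the standard log-variance formula, which does not
  reproduce some printed table cells whose defining formula is unstated.
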