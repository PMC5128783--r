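---
title: "Methods: quantifying dairy-cow stress responses around robot scrapers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying dairy-cow stress responses around robot scrapers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When an autonomous robot scraper is introduced into a dairy barn, the
unpredictability of a moving machine can act as a stressor. Stress in
cattle is conventionally read from three complementary channels:

* **cardiac vagal tone** — the time-domain heart-rate-variability index
  RMSSD (root mean square of successive interbeat-interval differences,
  ms), which falls under sympathetic activation;
* **behaviour** — daily time budgets of lying, feeding, standing (in the
  cubicle and in the walking area) and locomotion, which shift when
  animals re-organize their day to avoid an aversive stimulus;
* **adrenocortical activity** — fecal 11,17-dioxoandrostane (11,17-DOA)
  cortisol-metabolite concentrations, a non-invasive readout lagging
  secretion by roughly half a day.

`herdstress` implements the complete analysis pipeline for a
repeated-measures design with 3 farms x 12 cows and four one-week
periods: a baseline (B) before the robot is introduced and three test
periods (T1, T2, T3) with the robot operating. Because no animal
recordings are publicly deposited for such studies, the package pairs
every analysis stage with a synthetic-herd generator that reproduces the
design, so the whole chain is testable end to end.

## Interbeat-interval quality control

Telemetric RR recordings in loose housing are artifact-prone (belt
displacement, poor electrode contact). The pipeline screens each series
sequentially: interval *i* is flagged when it deviates from the running
reference by more than 20% (`qc$threshold`). The reference is the
*corrected* predecessor — a flagged interval does not update it — so a
single artifact cannot cascade into flags on its normal successors. The
forward-propagating reference is our reading of the sequential screen;
the direction of propagation is not prescribed by the source procedure,
and the threshold is config-exposed.

Flag runs are then typed against a robust local baseline (median of the
5 most recent unflagged intervals, `qc$median_window`):

| pattern | type | correction |
|---|---|---|
| two flags straddling the baseline, sum ~ 2x baseline | 2/3 | merge, halve |
| two flags both < 0.75x baseline, sum ~ baseline | 5 | merge |
| single flag > 1.75x baseline | 4 (missed beat) | split in two |
| any other single flag | 1 | linear interpolation (mean of flanking unflagged intervals) |
| run of 3+ flags | untyped | none; window rejected |

The 1.75 and 0.75 factors operationalize "markedly too wide" and "too
narrow": a missed beat doubles an interval (~2x) while boundary jitter
produces ~1.2-1.5x excursions, so 1.75 separates the two regimes. Both
constants are config-exposed (`qc$type4_factor`, `qc$type5_factor`).
Corrections of types 2-5 conserve the summed beat-train duration
exactly; type-1 interpolation changes it by less than one threshold
unit of the local baseline. Flagged intervals at a series boundary have
no flanking context and are dropped.

A 5-min window is **accepted** only if its corrected error rate
(flagged/total, counted before correction) is below 5% and it contains
no run of 3 or more flagged intervals. The error rate is counted on the
pre-correction flags because the acceptance rule is a statement about
recording quality, not about how well the corrections smoothed it.

## RMSSD windows

RMSSD is computed per 5-min window as `sqrt(mean(diff(x)^2))`. Windows
are time-defined: all intervals whose onset lies in `[t0, t0 + 300 s)`.
Selection is stratified by behavioural state to control for physical
activity: *active* windows (feeding or locomotion) are taken from the
noon-3 p.m. window, *rest* windows (lying) from 9 p.m.-midnight. The
earliest 5-min span in which the qualifying behaviour is continuous and
the excerpt passes QC is used; candidate starts advance in 60-s steps
within each behaviour span. One window per cow-day-state is emitted;
absence (no qualifying 5-min bout, or QC failure) is recorded as
missing data, the same missingness mechanism a real study faces.

Robot-proximity pairs take, per robot route pass, the 5 min centred on
the pass's distance minimum (*near*) and maximum (*far*), requiring
lying continuity and QC acceptance, discarding windows whose extremum
lies within 2.5 min of the 10 a.m.-3 p.m. boundary, and shifting an
overlapping far window to the next pass. The first pass yielding a
complete pair is used.

## Time budgets

Behaviour states are mutually exclusive and exhaustive: lying, feeding,
standing in the cubicle, standing in the walking area, locomotion, and
a remainder class `other`. Budgets are minutes per observed day over
three windows totalling 14 h (midnight-4 a.m., 10 a.m.-3 p.m.,
7 p.m.-midnight), all half-open so "to midnight" introduces no double
counting. Events crossing a window boundary are clipped; milking and
handling times can be excluded, which shortens the observed total
accordingly. `standing_total` is derived as the sum of the two standing
states, and feeding is disjoint from standing even though feeding cows
stand — under this reading the five states plus `other` partition the
observed day exactly.

## Mixed models and period contrasts

Each response is transformed before fitting: double log
(`log(log(x))`) for RMSSD, log for 11,17-DOA, square root for
standing-related budgets, identity otherwise. We read "double
logarithmic transformation" literally as `ln(ln(x))` of the ms-scale
RMSSD; an `ln(ln(x + 1))`-style variant would only relabel the
transformed scale, and both are monotone, so contrast signs are
unaffected. The transform map is configurable.

The model for every response is a Gaussian linear mixed model with
period as fixed effect and random intercepts for farm, cow within farm,
and cow x period — the interaction absorbs individual drift over the
study (for example progressing gestation). Fitting is by REML through
`lme4`; the package computes its own Satterthwaite machinery on top:

* the restricted log-likelihood is re-implemented as a function of the
  variance components (`herdstress:::reml_nll`), and its
  finite-difference Hessian (relative step `1e-5`) at the estimates
  gives the asymptotic covariance of the variance components;
* for a contrast `c`, `Var(c'beta) = c'(X'V^-1 X)^-1 c` is
  differentiated (same step) and the delta method yields
  `df = 2 Var(c'beta)^2 / Var-hat(Var(c'beta))`;
* components estimated on the zero boundary are held fixed and excluded
  from the information matrix. In the all-zero limit the df reproduce
  the OLS residual df `N - p`, which the test suite checks.

Observations with standardized marginal residuals outside the central
99% of the standard normal (|z| > 2.5758) are removed in a single pass
and the model refitted once; single-pass trimming matches the small
removal counts such studies report. Pairwise period contrasts are
t-tests on the transformed scale with the Satterthwaite df; no
multiplicity adjustment is applied by default, mirroring the original
reporting (a Holm option would be a one-line wrapper and is deliberately
not switched on). Reported per-period means and SEMs are raw-scale
arithmetic means of the analyzed observations — the scale on which such
results are printed — while all tests live on the transformed scale.

The proximity model adds robot position (near/far) and its interaction
with period (test periods only) to the fixed part and reports the
near-vs-far contrast within each test period.

## The synthetic herd: what it does and does not emulate

The generator states one fixed world; its defaults are not tuning
knobs.

* **Cohort structure.** Latent cow-period values are period mean + farm
  + cow-within-farm + cow x period effects, independent Gaussians. The
  period means use the printed study values where available (e.g.
  active-state RMSSD 6.83 ms and rest 9.02 ms in B, lying 320.77 and
  feeding 123.83 min in B, 11,17-DOA 15.36 in B). Values the study
  never printed (active RMSSD in T2/T3, lying in T1, feeding in T1/T3,
  locomotion in B/T2, cortisol in T1) are package defaults chosen once
  to be consistent with its narrative. **All variance-component sds are
  invented** — the study reports none — and are calibrated only to give
  SEM magnitudes of the same order as published figure error bars.
  Day-level replicates vary around the cow-period latent with a 5% cv.
  Positive responses are floored at 2% of the period mean; RMSSD
  additionally at 1.5 ms so the double-log transform stays defined (a
  healthy cow's RMSSD does not approach zero).
* **IBI series.** Intervals are i.i.d. truncated Gaussians with sd
  `true_rmssd/sqrt(2)`, making E[RMSSD] equal the target analytically.
  This is deliberately not a physiological point process — no
  respiratory sinus arrhythmia, no autocorrelation — because only the
  time-domain RMSSD is analyzed, and an i.i.d. model keeps the truth
  controllable. Consequences for realism (e.g. spectral indices) are
  out of scope.
* **Artifacts.** Missed beats (adjacent intervals summed), spurious
  beats (an interval split at a uniform(0.3, 0.7) point), boundary
  jitter (a beat time displaced by 35% of the local interval) and lone
  outliers (one interval scaled by a factor outside [0.8, 1.25]) are
  planted at non-adjacent sites. The first three conserve total
  duration to machine precision; a lone misread value cannot, and the
  conservation property is asserted for the conserving mechanisms. The
  default contamination is 2% of intervals (below the 5% rejection
  threshold); a stress preset at 8% exercises window rejection.
* **Behaviour.** An alternating-renewal process with exponential bouts
  (means: lying 40, feeding 20, standing 10, locomotion 2, other 10
  min). Each observation window is started in the stationary regime
  (initial state by occupancy probability, residual duration
  exponential by memorylessness), so the expected occupancy equals the
  latent budget *exactly* at any window length — this is what makes the
  parameter-recovery checks sharp. Bout-duration distributions, diurnal
  structure within windows, and habituation dynamics are not modelled.
* **Robot and cortisol.** The robot traverses a rectangular pen
  perimeter at the configured farm speed (4.0 or 5.5 m/min) through
  10 a.m.-3 p.m., sampled at 1 s; distances are Euclidean to a fixed
  lying position. Cortisol samples are log-normal with median equal to
  the latent concentration and log-sd `log(1 + cv)`, cv 0.2, three
  samples per cow-period (collection days 2, 3, 5).

A green recovery test therefore establishes that the pipeline is an
unbiased estimator *of this stated world's truth* at the study's
scale — not that the original animal data would reproduce, and not that
the invented variance components are biologically correct.

## Numerical choices and degenerate inputs

* QC detection needs at least 2 intervals; the first interval is never
  flagged (no predecessor).
* The local-baseline fallback near the series start is the median of
  all unflagged intervals.
* Candidate window starts advance in 60-s steps — a compromise between
  the unspecified "which 5-min span" rule and runtime; the earliest
  qualifying start wins, and ties in distance extrema resolve to the
  earliest second.
* REML convergence and boundary handling are delegated to `lme4`
  (the established fitter for exactly this model class); the package's
  own restricted likelihood is used for inference about the variance
  components and is verified in tests against a closed-form balanced
  one-way oracle and against perturbation of the optimum.
* Finite-difference steps are `1e-5` relative with a `1e-8` absolute
  floor; Satterthwaite df must come out positive or an error with the
  offending denominator is raised.
* Outlier removal refuses to empty a grouping level, and a removal pass
  that drops nothing returns the original fit unchanged.

## Known limitations

* The IBI text dialect is a stand-in; vendor formats of telemetric
  monitors are proprietary and out of scope.
* How the vendor software's own correction interacted with the
  five-type manual procedure in the original workflow is unknowable
  from the text; only the five-type procedure is implemented.
* Whether "corrected error rate" counts flags before or after
  correction is not stated at the source; this package counts
  pre-correction flags.
* The generator's variance components are free parameters; analyses
  that depend on their absolute size (power, coverage at other scales)
  should treat the defaults as illustrative.
* With 3 farms the farm variance component is estimated from 3 levels;
  its estimate is noisy and frequently on the boundary, which is
  expected behaviour, not a defect.
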