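---
title: "How many monitoring days? Methods behind actdays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many monitoring days? Methods behind actdays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actdays)
```

## The question and the model

A wrist accelerometer worn for a handful of days yields day-level values of
each physical-activity construct: overall activity (mean ENMO in mg),
light-activity minutes, bouted MVPA minutes. Treat days as exchangeable
replicates of a subject's habitual level:

$$y_{ij} = \mu + b_i + \varepsilon_{ij}, \qquad
  b_i \sim N(0, \sigma_b^2), \quad \varepsilon_{ij} \sim N(0, \sigma_w^2).$$

The single-day reliability is the intraclass correlation
$\rho = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$: the fraction of one day's
variance that is stable between-subject signal rather than day-to-day
noise. We estimate it with the one-way random-effects, single-measurement
form from the ANOVA mean squares,
$\widehat\rho = (MS_B - MS_W)\,/\,(MS_B + (k-1)MS_W)$, in
`icc_single_day()`.

Averaging $k$ days shrinks the noise term by $1/k$, which is the
Spearman–Brown prophecy $r_k = k r_1 / (1 + (k-1) r_1)$
(`spearman_brown()`). Inverting it at a target reliability gives the
minimum number of monitoring days (`min_days()`); with the conventional
target of 0.70, a protocol whose $k$-day average exceeds it is deemed to
capture 70 % construct and 30 % noise.

Assumptions worth stating plainly: days are exchangeable (no
autocorrelation, no learning or reactivity effects), the construct is
stable over the monitoring window, and error variance is homogeneous across
subjects. Day-of-week structure violates exchangeability mildly; the
descriptives module exists to show how much.

### Which ICC, and why

Only "the ICC of a single day" is pinned down by the analysis this package
operationalises; the estimator family is not. We use ICC(1,1) — one-way
random effects, single measurement — because the prophecy's "one day
$\to$ $k$ days" logic presumes days are interchangeable replicates with no
shared day effect, which is exactly the one-way model. Two-way forms that
remove a day main effect would treat, say, a rainy Wednesday shared by all
subjects as signal to be discarded; in a free-living protocol days are not
crossed with subjects in that sense (subjects start on different dates), so
the one-way form is also the honest one. The construct generator reports
both the plain truth $\sigma_b^2/(\sigma_b^2+\sigma_w^2)$ and the value the
one-way estimator targets when fixed day-of-week offsets are present
(inflated $MS_W$: $\sigma_b^2/(\sigma_b^2+\sigma_w^2+V_d)$ with
$V_d = \sum_j (d_j-\bar d)^2/(k-1)$), so tests can check either.

Negative ICC estimates (possible when the truth is near zero) are reported
and flagged, never clamped; the prophecy is refused for $r_1 \le 0$ as a
domain error, because averaging more days of pure noise predicts nothing.

### Minimum-days boundary semantics

`min_days()` uses a strict inequality by default (the "> 0.70" reading), so
$r_1 = 0.70$ needs two days, not one. The closed form
$k = \lceil t(1-r_1)/(r_1(1-t)) \rceil$ is verified by direct evaluation,
which settles ties the ceiling cannot. Callers can flip `strict = FALSE`.

A caution from our own validation work: the inversion is a step function of
$\widehat\rho$. When the true ICC sits near a boundary (e.g. 0.4375, where
the 0.70-target answer flips between 3 and 4 days), sampling error of even
$n = 500$ subjects (SD of $\widehat\rho \approx 0.02$ at $k = 6$) makes the
estimated minimum days land off the true value in a sizeable fraction of
replicates, however good the estimator. Parameter-recovery tests therefore
check the minimum-days match at an ICC chosen away from the boundaries
(0.623), and the mean-ICC recovery separately at an ICC near one (0.4525).

## The processing chain and its tunables

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `epoch_len` | 5 | s | epoch averaging window for ENMO |
| `mvpa_threshold` | 100 (exclusive) | mg | MVPA cut-point |
| `lpa_low` | 50 (inclusive) | mg | lower bound of the light band |
| `bout_min`, `bout_fraction` | 10, 0.8 | min, – | bout criterion |
| `min_wear_hours` | 16 | h | valid-day criterion |
| `min_valid_days`, `k_keep` | 6, 6 | days | analytical sample |
| `reliability_target`, `K` | 0.70, 6 | –, days | inversion target, curve length |
| `clip_g` | 8 | g | device dynamic range |
| non-wear window/step | 60 / 15 | min | sliding vote |
| non-wear SD / range | 13 / 50 | mg | per-axis stillness, ≥ 2 of 3 axes |

Band boundaries: MVPA is strictly above 100 mg, so 100 mg itself is light;
"between 50 and 100 mg" is read with both ends inclusive. Both are exposed
as configuration, since cut-point conventions differ across studies.

**Autocalibration.** A motionless, perfectly calibrated device reads
exactly 1 g whatever its orientation, so per-axis offset and gain are
estimable from still windows (10-s windows, per-axis SD < 13 mg) spanning
enough orientations. `autocalibrate()` iterates weighted least squares
toward the unit sphere (each round regresses the calibrated vectors on
their sphere projections, weights inversely proportional to distance from
the sphere, compounding offsets and gains). If fewer than 10 still windows
exist, or any axis never changes sign across window means (offset and gain
are then not separable on that axis), the identity model is returned with
`converged = FALSE` rather than a badly extrapolated fit, and the error
before/after (mean |magnitude − 1 g| in mg) is reported either way.

**ENMO.** The canonical definition truncates negative values of
$\lVert v\rVert - 1$ g to zero before epoch averaging: negatives can only
come from noise or calibration error, and truncation keeps still periods at
exactly 0 mg. A `negatives = "absolute"` switch preserves the
absolute-value reading for sensitivity analysis; on a signal alternating
between 1.2 g and 0.9 g magnitude the two give 100 vs 150 mg, which is the
scale of the dialect difference.

**Non-wear.** An unworn device lies still: 60-min windows stepping 15 min
vote non-wear when at least two axes are still by both SD and range; an
epoch is non-wear if any covering window votes yes. Consequences of this
design: detected gaps are resolved no finer than the step, edge windows
blur boundaries by up to one window, and a recording shorter than one
window is assumed worn (with a warning). Wear = not non-wear and not
abnormal. We deliberately do not impute non-wear time when averaging ENMO
over a day — overall PA is the mean over observed wear only — because any
imputation model would inject assumptions the 16-h validity criterion
already guards against. This is the main dialect risk against pipelines
that do impute, and it is confined to `summarize_day()`.

**Bouts.** "At least 80 % of a ≥ 10-min period in MVPA" names a criterion,
not an algorithm, and published implementations differ. Ours is fully
specified and deterministic: a greedy left-to-right scan; a candidate bout
starts on an MVPA epoch and is the longest window starting there that (a)
spans ≥ `bout_min`, (b) has MVPA fraction ≥ `bout_fraction`, (c) ends on an
MVPA epoch, and (d) contains no non-MVPA run longer than
$(1-\text{fraction})\times\text{bout}_{\min}$ (2 min at defaults); non-wear
breaks a bout unconditionally; accepted bouts never overlap and the scan
resumes immediately after each. Every epoch inside an accepted bout counts
toward bouted MVPA minutes, interruptions included. The whole rule set is
verified against a brute-force oracle that enumerates all windows
satisfying (a)–(d) and applies maximal earliest-start/longest-window
selection; the tests run a thousand random label sequences of up to 300
epochs through both. One numerical footnote: interruption and minimum-span
limits are computed with a $10^{-9}$ guard because
$(1-0.8)\times 600/5$ is 23.999… in floating point while the intended limit
is 24 epochs.

**Days and samples.** Days are local calendar days, midnight to midnight,
because day-of-week and weekday/weekend contrasts only make sense on
calendar alignment; partial first and last days are dropped. A day is valid
at ≥ 16 h wear; subjects with ≥ 6 valid days keep their first 6 in
chronological order, giving balanced matrices (the ICC above assumes
balance; unbalanced input is an error, not silently patched).

## The synthetic cohorts

Three fidelity tiers trade realism for speed; all are seeded with one root
seed and per-subject child streams (drawn once in subject order, so subject
$i$'s data survive a change in cohort size).

* **Construct tier** (`simulate_construct_matrix()`): draws the one-way
  model directly, plus fixed day-of-week/weekend offsets, with the
  closed-form ICC as attached ground truth (exact when negative-value
  truncation is off, the default). Thousands of subject-days in
  milliseconds; this is what reliability validation runs on.
* **Epoch tier** (`simulate_epoch_series()`): a minute-level Markov chain
  over sleep/sedentary/light/MVPA states with day and night transition
  regimes, log-normal subject, day and epoch multipliers, a weekend factor
  scaling transitions into active states, and occasional non-wear gaps.
  Emits per-epoch ENMO and wear flags directly; a 100-subject week is a
  desk-scale computation, which is why the end-to-end pipeline defaults to
  this tier.
* **Raw tier** (`simulate_raw_recording()`): per-sample tri-axial signal —
  a slowly re-orienting unit-gravity vector whose magnitude carries a
  non-negative state-dependent activity deviation (so true per-epoch ENMO
  is known exactly), white sensor noise, then injected calibration error
  (`measured = true/gain + offset`), perfectly still noise-free non-wear
  windows, and spike artifacts beyond ±8 g. `simulate_still_recording()`
  additionally provides the orientation-rich motionless input that
  calibration recovery needs.

What the generators deliberately do not emulate: realistic gait/posture
waveforms and their frequency content, autocorrelated day-to-day behaviour,
reactivity to being measured, temperature effects on the sensor, and
sociodemographic covariate structure. Passing tests therefore demonstrate
that the algorithms recover known truth under the stated noise model — not
that field recordings satisfy that model. The construct-tier defaults were
chosen once to mimic plausible cohort magnitudes (overall PA around 35 mg
with a single-day ICC near 0.44, i.e. $\sigma_b = 8$, $\sigma_w = 9$ mg,
and a modest weekend deficit); they are inputs to validation, not outputs
of it.

## Problem sizes and determinism

The shipped tests validate at sizes chosen for desk-scale runtimes: ICC
recovery on 500-subject × 6-day matrices over 20 seeds; bout-oracle
equivalence on 1,000 sequences ≤ 300 epochs; signal recovery on single
simulated days at 5–20 Hz; and the full pipeline determinism check on a
100-subject × 7-day epoch-tier cohort run twice and compared byte for byte.
Raw-tier validation uses reduced sampling rates because the algorithms are
rate-agnostic by construction (thresholds are in physical units, windows in
seconds); nothing in the implementation is specific to 85.7 Hz beyond the
default epoch alignment, which tolerates a half-sample mismatch per epoch.

All randomness flows from explicit seeds; re-running any stage with the
same configuration reproduces outputs bit for bit, and the RNG state of the
calling session is restored after every generator call.

## Known limitations

* Rank tests on day-of-week medians pool subject-days as independent
  observations, understating p-value uncertainty from within-subject
  clustering; this mirrors common descriptive practice and is flagged here
  rather than "fixed", since the reliability analysis, not the descriptive
  tests, is the package's inferential core.
* Sleep is not excluded, so overall PA includes nocturnal movement.
* No confidence intervals on minimum days; the step-function sensitivity
  discussed above means a bootstrap interval would often span adjacent
  integers, and adding one is left as an extension hook.
* Non-wear detection is acceleration-only (no temperature channel) and its
  epoch-level fallback, which sees only ENMO rather than per-axis signals,
  is an approximation for pre-aggregated inputs.
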