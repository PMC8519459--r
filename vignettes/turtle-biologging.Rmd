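---
title: "Methods: behaviour and time budgets from multi-sensor turtle tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behaviour and time budgets from multi-sensor turtle tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

A small archival tag glued to the carapace of a freshwater turtle records
tri-axial acceleration at 10 Hz and ambient temperature, pressure and light
at 1 Hz.  From these four channels alone, `pondlogger` reconstructs what the
animal did: it splits acceleration into a static (gravity/posture) and a
dynamic (movement) part, derives VeDBA — the norm of the dynamic vector, a
standard proxy for locomotor activity — together with pitch and roll;
segments every 24-h cycle into a Night, Morning, Midday and Evening phase
from threshold rules on 1-min statistics; finds breathing bouts (clusters of
transient pressure dips while the animal rests at the surface), basking
(sustained tag-temperature rises during emersion), dives (sudden temperature
drops or pressure rises) and nest digging (stereotyped rear-leg movements
that produce high pitch variance with low roll variance); infers the
occupied water stratum by regressing tag temperature on reference
temperature series; and finally aggregates everything into daily time and
activity budgets aligned on the egg-laying date, plus a logistic model of
daily basking occurrence driven by weather.

## Signal model

The decomposition uses a zero-phase 4th-order Butterworth low-pass whose
cutoff is tied to a 2-s window (0.5 Hz at 10 Hz sampling), applied
forward–backward so that features are not shifted in time.  `signal::filtfilt`
applies no padding, so the package reflects ~30 s of signal about each
endpoint before filtering; this reduces the edge error on a constant series
below 1e-10.  Half a window at each stream end is still flagged and excluded
from event detection.  A centred 2-s moving average is available as a
configuration alternative.  By construction `static + dynamic = raw` exactly
on every sample, and VeDBA is rotation-invariant — both properties are
enforced by tests.

Angles come from the static vector with the logger mounted on top of the
carapace, heave axis approximately vertical when level:
`pitch = atan2(sx, sqrt(sy^2 + sz^2))` (nose-up positive, so a vertical
posture `(g, 0, 0)` gives +90°) and `roll = atan2(sy, sz)`, both in degrees.
Samples whose static norm is below 0.1 g carry no usable gravity direction
and are flagged rather than raised as errors.  Pressure is surface-referenced
(0 bar at the surface, 0.1 bar per metre), so depth in cm is `1000 × P`,
with small negative readings clipped to zero and counted.

## Phase segmentation

Statistics are computed over consecutive non-overlapping 60-s epochs
(sample sd, n−1 denominator; an epoch needs ≥ 50 valid 1 Hz samples).  An
epoch is *night* when median light < 1000 lux **and** sd(T) < 1 °C **and**
sd(P) < 5e-3 bar; it is *midday* when mean light > 20 000 lux **and** the
epoch temperature is at least 2 °C above the running 24-h minimum.  The
2 °C excess operationalises "several degrees above the daily minimum",
which has no published number; it is configurable.  An epoch matching both
rules is labelled night — the night rule is a conjunction of three
conditions and therefore the more specific one.

Raw labels flicker at dawn and dusk, so each label sequence is smoothed by
morphological closing (gaps ≤ 5 min filled) and opening (runs < 10 min
dissolved).  Cycles are anchored on Night onsets rather than calendar
midnight, because all other phases are defined relative to Night; the cycle
date is the date at Night onset.  Within a cycle, Midday is the longest
surviving midday run; Morning fills Night-end → Midday-start and Evening
Midday-end → next-Night-start.  When no Midday survives (overcast days),
the whole inter-Night span is Morning and no Evening is emitted — this
matches the published bout counts, where Morning outnumbers Midday.

## Event detectors

*Breathing.*  The baseline is a 120-s running median of Night pressure; an
inhalation is a local pressure minimum at least 2 cm of water below
baseline, with a 5-s refractory period so one surfacing is never counted
twice (typical spacing between inhalations is ~17 s).  Events ≤ 60 s apart
group into bouts: at that gap a typical bout (≈ 10 inhalations over
≈ 2–3 min) stays together while inter-bout intervals of ≈ 20 min never
merge.  The 2-cm amplitude threshold is a tunable default derived from the
observed ~4.4 ± 3.1 cm surfacing rises, not a published constant.

*Basking and diving.*  Basking is a maximal run where the 60-s-smoothed
temperature is non-decreasing (within 0.01 °C per sample of noise
tolerance), lasting ≥ 5 min with a run-average slope ≥ 0.2 °C/min.  A dive
opens when temperature falls ≥ 2 °C over 60 s or pressure rises ≥ 0.01 bar
over 30 s; the two triggers merge within 60 s and the first sensor to fire
is recorded.  The published description gives no magnitudes for "sudden",
so all four numbers are explicit, configurable defaults.

*Nest digging.*  A 2-min window of the 10 Hz angle series is flagged when
`var(roll) < 50 & var(pitch) > 120` or `var(roll) < 10 & var(pitch) > 40`
(degrees²; the thresholds are only plausible in squared degrees).  Windows
slide every 30 s; flagged windows merge across gaps ≤ 10 min and merged
runs ≥ 5 min become events.  Acceleration alone cannot distinguish a
successful laying from an attempt, so events count as attempts unless they
match an observed nesting time in the metadata.

*Validation.*  A detection overlapping any truth interval is a true
positive, an unmatched detection a false positive, an unmatched truth
interval a false negative; FP% = FP/(TP+FP)·100 and FN% = FN/(TP+FN)·100.
Whether the original validation matched events by overlap or by counts per
window is not stated; overlap matching is used here.

## Stratum inference and the basking model

Outside Night the pressure channel is too erratic for depth (the tag bangs
into vegetation), so the occupied stratum is the reference series — air,
water surface, 20 cm, bottom, linearly interpolated from 10-min cadence —
whose OLS fit to tag temperature is closest to the identity.  The informal
"intercept ≈ 0, slope ≈ 1, R² ≈ 1" is operationalised as the score
`(1 − R²) + |slope − 1| + |intercept|/10`, i.e. 1 °C of intercept error
trades against 0.1 of R²; the score is zero only for an exact identity fit
and ties below 1e-6 are flagged ambiguous.  Both bout-wise and pooled
fitting are exposed, since the original report is explicit only about the
pooled Night regression.

Daily basking occurrence (Midday present yes/no per individual-day) is a
logistic regression on standardized weather covariates — daily mean cloud
fraction, daily rainfall sum, daily mean air temperature, day length — with
backward AIC selection (drop the single term whose removal lowers AIC most;
alphabetical candidate order makes ties deterministic).  The original
analysis used a binomial GLMM with individual as a random intercept; here
the individual effect is a **fixed** per-individual intercept by default.
With few individuals and hundreds of days each, the shrinkage a random
intercept would add is negligible, and the fixed-effect route is
deterministic and dependency-free; an exact random-intercept fit (e.g. via
`lme4::glmer`) is a drop-in alternative for users who want it.  Which
temperature variable entered the original model is unstated; daily mean
air temperature is the default here.

One property of AIC-based backward selection is worth keeping in mind: a
term is dropped exactly when its likelihood-ratio statistic is below 2,
and under the null that statistic is χ²(1)-distributed, so a pure-noise
predictor survives selection with probability P(χ²₁ ≥ 2) ≈ 15.7 %
whatever the sample size.  The test suite checks the observed drop rate
against this closed form rather than against an idealised "noise is always
removed" expectation.

## "Hourly VeDBA" and budgets

The published tables report phase durations and "hourly VeDBA" in m s⁻¹
without stating the formula.  Here it is defined as the VeDBA time-integral
over the phase divided by the phase duration in hours: a constant VeDBA of
0.16 m s⁻² yields 0.16 × 3600 = 576 m s⁻¹ regardless of phase length, which
reproduces the printed magnitudes (night ≈ 420, daytime ≈ 550–620,
egg-laying ≈ 1100 m s⁻¹).  Integrals use the trapezoid rule with linearly
interpolated endpoints, so integrals over adjacent bouts add exactly and
per-phase integrals conserve the daily integral whenever the bouts tile the
cycle (tested at 1e-6 relative tolerance).  Daily VeDBA spans Night-anchored
cycles, not calendar days; a cycle is complete when ≥ 95 % of its samples
are present.  Alignment day 0 is the first successful laying.

## What the generator emulates — and what it does not

The synthetic generator exists so that every stage can be validated with
known truth; its defaults are the study conditions.  Per day and
individual it schedules: behavioural night from sunset + 1 h to
sunrise − 1 h (day length from the solar-declination formula at 47.6° N);
a Midday basking block whose daily occurrence follows a logistic function
of cloud and day length (cloud fraction is a daily AR(1) process, and
> 0.9 cloud effectively suppresses basking); bask/dive cycles inside
Midday (linear warming ramps at 0.4 °C/min toward an air-plus-solar cap,
90-s dive decays, 2–4-min submerged interludes); nest digging on evenings
inside a configurable window (≈ 73 ± 38 min, amplitude-15° pitch
oscillation at 0.2 Hz giving pitch variance ≈ 112 deg² against a 2°
posture walk); and nightly breathing bouts (≈ 9.6 inhalations spaced
≈ 17 s, bouts ≈ 22.5 min apart, surfacing rises 4.4 ± 3 mbar) over a
0.037 ± 0.016 bar night resting depth.

Three generator choices deserve explanation:

* **Pressure noise is 5e-4 bar** (≈ 0.5 cm of water, a realistic archival
  sensor resolution).  The 2-cm inhalation threshold then sits at ~4 sigma
  of sensor noise, as it plausibly did on the real tags.
* **Swimming pressure is an erratic reflected random walk** (0.006 bar
  steps at 1 Hz).  The field observation the segmentation relies on is that
  pressure is "highly variable" outside Night; the step size is set so a
  1-min window sd is far above the 5e-3 bar night threshold.
* **Digging ends at least an hour before sunset.**  A motionless turtle on
  land in darkness is indistinguishable from a resting one by the
  light/temperature/pressure rules, so late-night digging would corrupt the
  phase truth labels; most real nesting is crepuscular, and the angle-based
  dig detector is unaffected by this restriction.

Dynamic noise per axis is white with sd chosen so the *measured* VeDBA
matches the configured state target: for three iid normal axes
E[VeDBA] = σ·√2·Γ(2)/Γ(3/2) ≈ 1.5958 σ, and the 0.5 Hz decomposition
retains ρ ≈ 0.886 of white-noise variance in the dynamic part, giving a
calibration constant 1.5958·√ρ ≈ 1.502 (verified numerically in the test
suite).  State targets are rest 0.117, forage/evening 0.17, bask 0.15,
dig 0.31 m s⁻², whose hourly integrals reproduce the published per-phase
magnitudes.

The generator does **not** emulate: heavy-tailed activity distributions
(all noise is normal or Poisson-like), biophysical heat transfer (ramps are
linear, dives exponential), sensor drift or dropouts, social interactions,
or movement between ponds.  Passing the synthetic recovery tests therefore
shows the *algorithms* implement their rules correctly under realistic
signal-to-noise, not that the thresholds are optimal for any particular
field data set.

Clock drift is linear at ≈ 21 min per 141 days; streams are returned on the
drifted logger clock and corrected through the RTC anchor pairs by
piecewise-linear interpolation (linear with two anchors — the minimal
assumption, since the original interpolation is unstated).

## Validation scope and problem sizes

Event-level validation on synthetic deployments is restricted to the
segmented span (first to last detected Night onset): the first and last
partial nights of a deployment are outside any complete night-to-night
cycle by construction, so the detector never searches them and counting
their truth events as misses would mis-state the detector's error.

The headline field results (per-phase means over 1096 turtle-days, GLMM
slopes, pooled R² values) come from an undeposited data set and are not
reproducible at desk scale.  The test suite therefore checks (a) the
self-contained arithmetic exactly — depth conversions, validation
percentages, deployment bookkeeping, mass ratio — and (b) recovery
properties on seeded synthetic deployments: the acceptance suite uses the
full default scale (8 individuals × 20 days, ≈ 28 M accelerometer samples
per individual), the unit suites a 1 × 6-day deployment, and the analysis
scripts a 3 × 10-day deployment.  Logistic-model recovery uses n = 1000
individual-days and 100 replicates of n = 300 for the backward-AIC noise
check.

## Known limitations

* Threshold detectors inherit threshold bias: a point just past a
  threshold flips an epoch, which is why labels are smoothed and bout
  durations are reported at 1-min resolution.
* The midday temperature-excess rule uses tag temperature, as the rule is
  written on the tag channel; whether the original used the field series
  instead is unknowable from the text.
* Inhalation amplitudes below the 2-cm threshold are undetectable by
  design; per-inhalation counts are therefore conservative even when bout
  counts are accurate.
* With a single pond and shared weather, individuals are conditionally
  independent given the environment — the generator mirrors this, so
  cross-individual pseudo-replication is *present* in synthetic designs,
  exactly as the per-individual intercepts assume.
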