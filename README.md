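# pondlogger

Behaviour, time budgets and activity proxies for freshwater turtles carrying
multi-sensor archival tags.

## The problem

European pond turtles (*Emys orbicularis*) are small, cryptic ectotherms:
direct observation misses most of what they do, especially at night, when
nesting females leave the water to dig. A carapace-mounted tag recording
tri-axial acceleration at 10 Hz plus ambient temperature, pressure and light
at 1 Hz captures months of behaviour — if the four channels can be decoded.
`pondlogger` is that decoder, written for movement ecologists working with
such deployments: it turns raw logger streams into phase-segmented days,
behavioural events, and daily time/energy budgets, and ships a seeded
synthetic deployment generator with ground-truth labels so every stage is
testable without field data.

## The method

* **Motion signal.** Each acceleration axis is split into a static
  (gravity/posture) and a dynamic (movement) component with a zero-phase
  4th-order Butterworth low-pass (2-s window, 0.5 Hz cutoff).
  VeDBA = ‖dynamic‖₂ is the activity proxy;
  pitch = atan2(sx, √(sy²+sz²)) and roll = atan2(sy, sz) come from the
  static vector; depth [cm] = 1000 × pressure [bar].
* **Phase segmentation.** Over 1-min epochs: *night* iff
  median(L) < 1000 lux ∧ sd(T) < 1 °C ∧ sd(P) < 5·10⁻³ bar; *midday* iff
  mean(L) > 20 000 lux ∧ T ≥ 2 °C above the running 24-h minimum. After
  label smoothing, cycles run Night-onset → Night-onset; Morning and
  Evening fill the spans around the longest Midday run.
* **Events.** Inhalations are ≥ 2 cm dips below a 120-s running median of
  night pressure, grouped into breathing bouts at a 60-s gap; basking is a
  sustained (≥ 5 min, ≥ 0.2 °C/min) temperature rise; dives are sudden
  temperature drops (≥ 2 °C/60 s) or pressure rises (≥ 0.01 bar/30 s);
  nest digging is flagged where var(roll) < 50 ∧ var(pitch) > 120 or
  var(roll) < 10 ∧ var(pitch) > 40 (deg², 2-min windows).
* **Stratum inference.** Tag temperature is regressed on four reference
  series (air, surface, 20 cm, bottom); the fit closest to intercept 0,
  slope 1, R² 1 wins.
* **Budgets & basking model.** Per-cycle phase durations, hourly VeDBA
  (integral per hour of phase, m s⁻¹), event counts, alignment to the
  laying date; daily basking occurrence is modelled by logistic regression
  on standardized weather covariates with per-individual intercepts and
  backward AIC selection.

The methods vignette (`vignettes/turtle-biologging.Rmd`) documents every
rule, default and design decision.

## Worked example

```r
library(pondlogger)

cfg <- generator_config(n_individuals = 1, n_days = 6, seed = 11,
                        nesting_window = c(2, 4))
env <- generate_environment(cfg)
ind <- generate_individual(cfg, 1, env)
ann <- annotate_deployment(ind$env, ind$accel, ind$meta, ref = env$ref)

head(ann$bouts[, c("cycle", "label", "duration_h")])
#>   cycle   label duration_h
#> 1     1   Night  2.9500000
#> 2     1 Morning  6.4000000
#> 3     1  Midday  5.5500000
#> 4     1 Evening  4.9000000
#> 5     2   Night  7.1833333
#> 6     2 Morning 17.1333333

ann$budgets[1:3, c("night_h", "night_vedba", "daily_vedba",
                   "n_breathing_bouts", "n_nesting_events")]
#>    night_h night_vedba daily_vedba n_breathing_bouts n_nesting_events
#> 1 2.950000    426.1286    11290.23                 8                0
#> 2 7.183333    426.8711    13604.39                19                0
#> 3 7.033333    426.9099    13910.68                19                1

evaluate_against_truth(ann, ind$truth)[c("phase_accuracy_pct", "breathing")]
#> $phase_accuracy_pct
#> [1] 96.91299
#> $breathing
#> $breathing$tp: 98   $fp: 6   $fn: 1
#> $breathing$fp_pct: 5.8   $fn_pct: 1
```

Night hourly VeDBA of ≈ 427 m s⁻¹ is the resting level (0.117 m s⁻² ×
3600); 97 % of 1-min epochs carry the correct phase; 98 of 99 true
breathing bouts are found with 6 false alarms; the one nest-digging bout in
cycle 3 is detected with mean VeDBA ≈ 0.31 m s⁻², about twice the
deployment-wide mean.

The numbered scripts under `analysis/` run the same pipeline as a
narrative: `01_simulate` → `07_basking_model`, each writing its tables
under `results/`.

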