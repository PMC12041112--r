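# avoidsim

Simulation and analysis of free-movement avoidance-conditioning
experiments.

## What this is for

In room-scale avoidance conditioning, a participant learns — by walking,
not by key presses — to avoid a conditioned stimulus (CS+) that predicts
an aversive sound (US), while a second stimulus (CS-) is always safe. The
US is 80 dB at its source and decays linearly by 25% per meter, so it is
inaudible beyond 4 m: the correct avoidance action is to walk away, and it
must be discovered by exploration. Avoidance is then measured continuously
from the head trajectory rather than as a categorical response.

avoidsim is a headless, desk-scale toolkit for this paradigm, aimed at
researchers who want to design such experiments, pilot their analysis
pipelines, or calibrate their statistics before collecting human data. It
provides:

* **a declarative task engine** — rooms, US sound fields, stimuli and
  phases described in JSON (+ optional per-trial CSV); five validated
  experiment templates (`exp1` ... `exp5`) combining Pavlovian
  acquisition, avoidance learning, transfer (incidental coin search),
  instructed extinction, extinction recall and reinstatement; exact
  per-participant schedules with 75% partial reinforcement, uniform
  9-15 s ITIs and parity counterbalancing;
* **simulated participants** — delta-rule learning agents (excitatory
  trace + extinction-built inhibition, so reinstatement works) with a
  distance-regulating movement policy, generating 90-Hz head-tracker
  traces;
* **session logging** — the one-row-per-trial table plus
  one-movement-CSV-per-tracker-per-trial layout of room-scale behavioural
  loggers, with readers, validation and handedness conversion;
* **kinematics** — the seven trial-level summary statistics over the
  CS-onset to US-onset window: mean/max/min distance to the CS, path
  length, maximum speed, head direction relative to the CS, and the
  0.7-m reaction time of the first move away;
* **statistics** — paired Cohen's *d*/Hedges' *g* with noncentral-t
  confidence intervals, the within-phase
  (`DV ~ CS * Trial_num + (1 | ppid)`) and across-phase
  (`DV ~ CS * Phase + Trial_num + (1 | ppid)`) mixed-model contrasts,
  and sensitivity power analysis for one-sided paired t tests.

## Worked example

Simulate a small cohort on the `exp2` design, compute the kinematic
summaries, and test the CS+/CS- difference in the primary measure (mean
distance from the CS):

```r
library(avoidsim)

spec <- experiment_template("exp2")
spec
#> <experiment_spec> exp2
#>   room 8 x 8 x 3 m; pedestal at (0, 1.1, 2.5); tracker 90 Hz
#>   US: 80 dB, 25%/m decay (inaudible beyond 4 m), 1 s, source visibly cued
#>   1. practice                0/cond, reinf 0%, CS 40 s, start 2 m
#>   2. pavlovian_acquisition   8/cond, reinf 75%, CS 9 s, start 2 m
#>   3. avoidance_learning      8/cond, reinf 75%, CS 9 s, start 1 m
#>   4. transfer                2/cond, reinf 0%, CS 21 s, start 2.5 m
#>   5. instructed_extinction   8/cond, reinf 0%, CS 9 s, start 4 m
#>   6. transfer                2/cond, reinf 0%, CS 21 s, start 2.5 m

cohort <- run_cohort(spec, n_participants = 8, seed = 1,
                     params = agent_population())
tab <- cohort_table(cohort)  # one row per trial, 7 kinematic columns

paired_effect_size(
  aggregate_by_condition(tab, "mean_dist_m", "avoidance_learning"))
#> <effect_size> d_z = 4.149, Hedges' g = 3.688, 95% CI [1.699, 5.665], n = 8 pairs
```

During avoidance learning the simulated cohort keeps a much larger mean
distance from the CS+ than from the CS- (a positive *g*; the simulator's
idealized agents produce larger standardized effects than human cohorts
do). The across-phase model shows the difference collapsing under
instructed extinction — a negative CS x Phase interaction of about 2 m:

```r
fit <- fit_cross_phase_model(tab, "mean_dist_m",
                             c("avoidance_learning", "instructed_extinction"))
fixed_effect(fit, "conditionCS+:phaseinstructed_extinction")
#>      estimate            se            df             t             p
#> -1.973830e+00  1.732010e-01  2.440000e+02 -1.139618e+01  2.105660e-24

sensitivity_dz(24)   # minimal detectable paired d at n = 24, 80% power
#> [1] 0.5231754
```

Kinematics can be hand-checked on the packaged fixture traces — a walker
going from 1 m to 4 m from the CS at 1 m/s, then standing still:

```r
summarize_trial(avoidsim:::fixture_traces(90)$straight_walk, c(0, 1.1, 2.5))
#> <kinematic_summary> dist mean/min/max 3.435/1.000/4.000 m, path 3.000 m,
#>   max speed 1.000 m/s, head angle 180.0 deg, RT 0.700 s (720 samples)
```

Sessions round-trip through disk in the standard layout: `write_session()`
writes `trial_results.csv`, `trackers/head_T###.csv`, `events.csv` and a
`spec.json` snapshot; `read_session()` and `augment_session_dir()` bring
recorded or simulated sessions back into the analysis pipeline.

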