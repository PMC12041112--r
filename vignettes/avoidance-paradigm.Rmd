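---
title: "Simulating and measuring free-movement avoidance conditioning"
author: "avoidsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring free-movement avoidance conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidsim)
```

## The paradigm

avoidsim models a room-scale avoidance-conditioning experiment. A
participant stands in an 8 x 8 x 3 m virtual room containing a pedestal on
which one of two conditioned stimuli (CS+ or CS-) appears for 9 s per
trial. On 75% of CS+ trials an aversive sound (US) plays for 1 s starting
8 s after CS onset, co-terminating with the CS. The sound is 80 dB at its
source under the pedestal and decays linearly by 25% of the source
intensity per meter, so it is inaudible beyond 4 m: walking at least 4 m
away is the objectively correct avoidance action, and it must be
discovered by exploration, not instruction. Inter-trial intervals are
uniform on 9-15 s (mean 12 s).

An experiment is an ordered sequence of phases. The shipped templates
`exp1` ... `exp5` combine them as five validated designs:

* *practice* — a 40-s free-movement familiarisation without CS;
* *Pavlovian acquisition* — 16 seated trials (8 per condition) 2 m from
  the pedestal, no movement;
* *avoidance learning* — same contingencies, free movement, starting
  point 1 m from the CS;
* *transfer* — 21-s unreinforced CS presentations from 2.5 m while an
  incidental coin-collection task runs (coins appear for 1 s each in a
  2 x 2 m ellipse 1 m in front of the start, 1 m above the floor);
* *instructed extinction* — unreinforced trials from 4 m with an on-screen
  prompt to approach the CS;
* *extinction recall* — four uninstructed, unreinforced trials from 1 m;
* *reinstatement* — one unsignalled US followed by unreinforced trials
  from 1 m.

Designs are plain data: a JSON file fixes the room, US field, stimuli and
phase list, and an optional CSV fixes the per-trial features, so variants
can be versioned and shared without code changes
(`load_experiment_config()`, `experiment_template()`).

Schedules are generated per participant: conditions are interleaved by a
uniform random permutation (an optional maximum run length supports
pseudo-randomisation but is off by default, since an unconstrained random
order is the reference behaviour), the reinforced CS+ trials are chosen
uniformly at random, and the CS-identity-to-condition mapping alternates
with participant parity. Parity-based counterbalancing is deterministic on
purpose: it makes cohorts exactly balanced and reproducible, where random
assignment would only be balanced in expectation. Reinforcement counts
that are not integers (e.g. a 70% rate with 8 trials) are rejected rather
than rounded, so a schedule is always exactly what its configuration
states. We deliberately leave the position of reinforced trials
unconstrained (no "no US on trial 1" rule): nothing in the design requires
one, and any constraint would bias trial-level learning analyses.

## The simulated participant

Human sessions are stood in for by a parametric agent
(`agent_params()`), with two components.

**Learning.** Each condition carries an excitatory association $V$ updated
once per trial by the delta rule
$V \leftarrow V + \alpha(\text{outcome} - V)$, whose fixed point under
Bernoulli reinforcement is the reinforcement rate. The *outcome* is the
perceived US: a delivered US counts only if the agent is inside the 4-m
audible radius at US onset, unless the experiment marks the source visibly
(the `vibration_cue` flag of `us_field()`, on in templates `exp2`
onwards). This reproduces the self-limiting character of avoidance in the
cue-less design: an agent that avoids successfully stops receiving
evidence.

A single delta-rule trace cannot show reinstatement — erasing $V$ during
extinction leaves nothing to recover. We therefore model extinction as new
inhibitory learning on top of a preserved excitatory trace: an inhibitory
association $I$ moves toward $V$ (rate $\alpha$) whenever an expected US
is omitted, behaviour is driven by $\max(0, V - I)$, and an unsignalled US
resets $I$ (fraction `reinstatement_reset`, default 1). Acquisition also
shrinks $I$ toward 0. This is the classic
extinction-as-inhibition account, and it is the minimal mechanism that
produces all three qualitative signatures at once: acquisition of a CS+/CS-
difference, its reduction under (instructed) extinction, and its return
after a reinstatement US. A `generalisation_weight` adds a fraction of the
effective CS+ association to the CS-, emulating perceptual generalisation
between similar stimuli.

**Movement.** Time advances in fixed steps of one tracker frame (default
90 Hz, within the 80-120 Hz range of room-scale headsets; variable frame
times add nothing at the trial level). When the effective association
exceeds `avoidance_threshold` and movement is allowed, the agent walks
away from the CS at `walk_speed` until `preferred_safe_distance` (default
4 m, the audible radius); under an instructed-approach prompt a compliant
agent (probability `approach_compliance` per trial) walks toward the CS
instead; otherwise it only sways. Sway is Brownian position noise
(`position_noise_sd` meters per axis per second), heading follows the
movement direction — or the CS bearing when stationary — plus Gaussian
noise. Positions are clipped to the room. The per-sample stepper is
compiled code but draws from R's RNG, so `set.seed()` governs everything.

`run_cohort()` derives one RNG stream per participant from the master
seed, so cohorts are reproducible and their first $k$ members do not
change when the cohort grows. `agent_population()` draws each
participant's parameters from plausible ranges (learning rate 0.15-0.45,
threshold 0.3-0.6, safe distance 3-4.5 m, walking speed 0.6-1.4 m/s,
compliance 0.8-1, generalisation 0-0.4); without such heterogeneity,
cohort-level standardized effect sizes are degenerate, because identical
agents produce near-identical condition differences.

What the simulation does *not* emulate: biomechanically realistic gait or
posture, eye movements, within-trial (continuous-time) learning,
forgetting between phases, or fitting of agent parameters to human data.
Passing tests therefore show that the *pipeline* — scheduling, logging,
kinematics, statistics — behaves correctly and that the paradigm's
qualitative learning signatures are recoverable from trajectories; they
do not validate quantitative predictions about human effect magnitudes,
which depend on the arbitrary agent parameter ranges.

## Session logs

Sessions are written the way room-scale behavioural loggers write them
(`write_session()`): a `trial_results.csv` with one row per trial, one
movement CSV per tracker per trial (`time_s, pos_x, pos_y, pos_z,
yaw_deg`; left-handed y-up frame, trial-relative time with 0 = CS onset),
an `events.csv` of timestamped markers (TTL-style rows: `cs_on`, `us_on`,
`coin_spawn`, ...), and a JSON snapshot of the experiment definition.
Storing tracker time per trial rather than per session keeps each trial's
kinematics self-contained; session-relative onsets live in the trial
table. The reader (`read_session()`) accepts common column aliases with a
warning, and refuses non-monotone timestamps or missing tracker files with
errors naming the offending trial. `convert_handedness()` maps traces to a
right-handed frame (z negated, yaw re-expressed); all kinematic quantities
are invariant when the CS position is co-converted, which the tests check.

## The seven trial-level statistics

From the head trace of each trial, over the window from CS onset to the
scheduled US onset (0-8 s), `summarize_trial()` computes: mean, maximum
and minimum distance to the CS; path length (summed consecutive-sample
displacement); maximum speed (consecutive-sample finite differences);
mean absolute head direction relative to the CS (0° = facing it); and the
reaction time of the first move away — the first time the head is
displaced at least 0.7 m from its CS-onset position, in any direction.
Reaction times are censored (`NA`) when the criterion is never met;
participants whose trials are all censored are dropped pairwise from RT
analyses, with the censoring count reported — imputing a value for
"never moved" would fabricate speed information.

Numerical choices, made once and tested:

* Distances use the horizontal (x, z) projection by default: locomotor
  avoidance is horizontal and the pedestal height is constant, so the
  vertical component only adds head-bob noise. A `"3d"` mode exists for
  paradigms where height matters.
* The window end is the *scheduled* US onset (8 s) for all 9-s
  conditioning trials, reinforced or not, so reinforced and unreinforced
  trials are measured on identical support. For 21-s transfer trials,
  which never schedule a US, the default window is the full CS period
  (configurable to a nominal 8-s cut).
* Speeds are raw finite differences with no smoothing. On jittery
  hardware traces this inflates path length and maximum speed; an optional
  centered moving-average smoother (`smooth_window`, off by default)
  trades temporal resolution for robustness.
* Window selection is half-open (`t0 <= t < t1`); an empty window or a
  single sample is an error, not a silent `NA`.

Every summary is checked against an independently coded brute-force
per-sample oracle on 1,000 random traces to 1e-9 relative tolerance, and a
hand-derived straight-walk fixture pins the closed-form values.

## The statistical layer

The primary criterion for a CS+/CS- difference within a phase is the
paired standardized mean difference on per-participant condition means:
$d_z = \bar{x}_{diff} / s_{diff}$ with Hedges'
$g = d_z\,[1 - 3/(4\,df - 1)]$, $df = n - 1$. We use $d_z$ because it is
the quantity the one-sided paired $t$ test is powered for; a $d_{av}$
variant (mean difference over the average condition SD) is available.
The 95% CI inverts the noncentral-t distribution of the paired $t$
statistic (a percentile bootstrap is the alternative). Degenerate input is
defined, not guessed: all-zero differences give $d = g = 0$ with a
degenerate CI, while a nonzero mean with zero variance is an error.

Trial-level contrasts use linear mixed models, fitted by `lmerTest` with
Satterthwaite degrees of freedom: within a phase
`DV ~ CS * Trial_num + (1 | ppid)` (trial number entered as a linear
numeric predictor with one degree of freedom), and across exactly two
phases `DV ~ CS * Phase + Trial_num + (1 | ppid)`, whose CS x Phase
interaction is the criterion for extinction (avoidance vs. extinction) and
reinstatement (extinction vs. reinstatement). Random slopes are not
attempted: with one random intercept the models converge reliably at
these sizes, and the package's contract is the model structure plus its
calibration, not a particular optimiser. If a fit fails to converge, a
repeated-measures ANOVA on participant-by-condition means is reported as
the fallback. No multiple-testing correction is applied; in a
many-DV exploratory setting the p values are descriptive, and the effect
sizes carry the inferential weight.

`sensitivity_dz()` inverts the exact noncentral-t power function of the
paired t test (numerically, to 1e-6): for 80% power at one-sided
$\alpha = 0.05$ it gives minimal detectable $d$ of about 0.54, 0.52, 0.45,
0.46 and 0.46 at $n$ = 23, 24, 32, 30 and 31. Published G*Power-style
tables for the same settings print values about 0.01-0.04 smaller; we
keep the exact computation rather than reverse-engineering a match, and
check instead that the function is strictly decreasing in $n$ and within
5% of the large-sample approximation
$(z_{1-\alpha} + z_{power})/\sqrt{n}$ for $n \ge 20$.

## Calibration and problem sizes

The suite calibrates the whole pipeline end to end, at sizes chosen to
keep a desk run comfortable:

* *Type-I error*: 200 cohorts of 24 non-learning agents
  (`null_agent()`, a zero learning rate) on a single 16-trial avoidance
  phase; the paired test and the LMM condition effect must each reject in
  5% ± 2.5% of cohorts at $\alpha = .05$.
* *Recovery*: 100 simulated trial tables with a known 1.0 m condition
  effect (participant SD 0.5, residual SD 0.5, 24 x 32 trials); the mean
  LMM estimate must sit within 0.1 of truth.
* *Direction*: a 24-agent heterogeneous cohort on the full
  acquisition-extinction-reinstatement design must show $g > 0$ for mean
  distance in avoidance learning, a negative CS x Phase interaction into
  instructed extinction, and a positive one from extinction to
  reinstatement. Only directions are asserted: the magnitudes depend on
  agent parameter ranges that have no empirical counterpart.
* *Dose-response*: across five graded avoidance-propensity levels
  (decreasing response thresholds, from an unattainable null level to one
  every agent crosses), cohort-level $g$ for mean distance increases
  monotonically (Spearman rank correlation on level means). Propensity is
  the right grading dimension for a *standardized* effect: grading vigor
  (walking speed) scales the mean difference and its between-participant
  SD together, so $g$ saturates instead of growing.

## Known limitations

Hand trackers are simulated only as a fixed forward offset of the head
(for coin collection); return walks during inter-trial intervals are not
instrumented; two-pedestal configurations are validated but not exercised;
and the alias shim for third-party tracker exports is best-effort, since
column vocabularies vary between logger versions. Agent parameter
estimation from real session data is out of scope — the reader and the
summary layer accept recorded sessions, but the package makes no claim
that its agents fit any particular human cohort.
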