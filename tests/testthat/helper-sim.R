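# Shared simulation fixtures, built in code.

# Single-phase free-movement design: 16 avoidance-learning trials with the
# standard contingencies and a visibly cued US source.
avoidance_only_spec <- function(tracker_rate = 90) {
  experiment_spec(
    name = "avoidance_only",
    phases = list(phase_defaults("avoidance_learning")),
    us = us_field(vibration_cue = TRUE),
    tracker_rate = tracker_rate)
}

# Per-participant condition means of a DV for one phase, as a paired table.
cohort_pairs <- function(cohort, dv = "mean_dist_m",
                         phase = "avoidance_learning") {
  aggregate_by_condition(cohort_table(cohort), dv, phase)
}
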