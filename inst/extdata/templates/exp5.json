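{
  "name": "exp5",
  "us": {"intensity_db": 80, "decay_per_m": 0.25, "duration_s": 1, "vibration_cue": true},
  "stimuli": [
    {"cs_label": "CS+", "shape": "cube", "color": [46, 61, 124], "size": [0.2, 0.2, 0.2]},
    {"cs_label": "CS-", "shape": "cylinder", "color": [222, 151, 11], "size": [0.24, 0.1, 0.24]}
  ],
  "phases": [
    {"phase_kind": "practice"},
    {"phase_kind": "avoidance_learning"},
    {"phase_kind": "transfer"},
    {"phase_kind": "instructed_extinction"},
    {"phase_kind": "extinction_recall"},
    {"phase_kind": "transfer"},
    {"phase_kind": "reinstatement", "n_trials_per_condition": 3, "pre_phase_us": 1}
  ],
  "tracker_rate_hz": 90
}
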