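{
  "name": "exp2",
  "us": {"intensity_db": 80, "decay_per_m": 0.25, "duration_s": 1, "vibration_cue": true},
  "phases": [
    {"phase_kind": "practice"},
    {"phase_kind": "pavlovian_acquisition"},
    {"phase_kind": "avoidance_learning"},
    {"phase_kind": "transfer"},
    {"phase_kind": "instructed_extinction"},
    {"phase_kind": "transfer"}
  ],
  "tracker_rate_hz": 90
}
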