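{
  "frame": ["phi1", "phi2", "phi3", "phi4"],
  "masses": [
    {"subset": ["phi1", "phi2"], "magnitude": 0.9055, "phase_tan": 0.1111},
    {"subset": ["phi3"], "magnitude": 0.1414, "phase_tan": -1.0},
    {"subset": ["phi4"], "magnitude": 0, "phase_tan": 0}
  ]
}
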