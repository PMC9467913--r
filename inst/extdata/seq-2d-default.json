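{
  "name": "2D default iteration sequence",
  "ndim": 2,
  "iterations": [
    {"id": "prelocalization", "L": null, "photon_limit": 160, "dwell_ms": 1, "cfr_limit": "off", "power_factor": 1},
    {"id": "iteration_1", "L": 288, "photon_limit": 150, "dwell_ms": 1, "cfr_limit": 0.5, "power_factor": 1},
    {"id": "iteration_2", "L": 151, "photon_limit": 100, "dwell_ms": 1, "cfr_limit": "off", "power_factor": 2},
    {"id": "iteration_3", "L": 76, "photon_limit": 100, "dwell_ms": 1, "cfr_limit": 0.8, "power_factor": 4},
    {"id": "iteration_4", "L": 40, "photon_limit": 150, "dwell_ms": 1, "cfr_limit": "off", "power_factor": 6}
  ]
}
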