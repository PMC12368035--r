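{
  "experiment": "pulse",
  "pump": {"cycle_rate": 0},
  "buffer": {"b_total": 10000},
  "pulse": {"influx": "step", "step_ca": 10}
}
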