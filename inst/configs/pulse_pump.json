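{
  "experiment": "pulse",
  "pump": {"cycle_rate": 20000},
  "buffer": {"b_total": 0},
  "pulse": {"influx": "pulse"}
}
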