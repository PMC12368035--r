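{
  "experiment": "steady",
  "pump": {"cycle_rate": 5000},
  "steady": {"c_pip": 10}
}
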