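{
  "experiment": "scan",
  "scan": {"rates": [50, 500, 5000, 20000], "mode": "steady"}
}
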