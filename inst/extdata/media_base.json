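{
  "nh3_e": 100,
  "co2_e": 100,
  "pi_e": 100
}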