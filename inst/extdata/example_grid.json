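{
  "t": 50,
  "T": 250,
  "theta_deg": 60,
  "u1": 0.25,
  "u2": 0.75
}
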