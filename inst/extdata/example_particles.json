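[
  {"id": "a", "ring": [[10, 10], [30, 12], [22, 28]]},
  {"id": "b", "ring": [[60, 40], [80, 40], [80, 60], [60, 60]]},
  {"id": "c", "ring": [[120, 15], [140, 20], [135, 38], [118, 32]]}
]
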