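# colonysim config v1 — rimless clone: identical to the rimmed reference
# except for the sensitivity triple (quorum-insensitive Qlim).
version: 1
params:
  N: 140
  P: 1
  S: 10
  A: 5
  O: 0.01
  D: 0.495
  G: 5
  Qlim: 1.0e6
  Olim1: 100
  Olim2: 1000
  L: 201
  max_generations: 500
inoculum:
  kind: POINT
  positions: [101]
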