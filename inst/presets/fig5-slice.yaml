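# Sweep spec: bit-string slice over peptides per pathogen (v = 7, m = 14)
base:
  model: bitstring
  N: 100000
  mu: 0.000005
  generations: 2000000
  seed: 1
  thin: 1000
  K: 1
  cmax: 1.0e+12
  m: 14
  npep: 3
  v: 7
axes:
  npep: [1, 3, 10, 20]
replicates: 1
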