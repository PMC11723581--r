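# Sweep spec: one-dimensional slice of the Gaussian v-K plane (m = 3, K = 0.1)
base:
  model: gaussian
  N: 100000
  mu: 0.0000005
  generations: 1000000
  seed: 1
  thin: 1000
  K: 0.1
  cmax: 4.3673179098e+10
  m: 3
  v: 7
  delta: 0.03
axes:
  v: [2, 3, 5, 7]
replicates: 1
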