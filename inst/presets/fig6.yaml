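# Bit-string model, 12 pathogens x 3 peptides, v = 7, K = 1
model: bitstring
N: 100000
mu: 0.000005
generations: 1000000
seed: 1
thin: 1000
K: 1
cmax: 1.0e+12
m: 12
npep: 3
v: 7
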