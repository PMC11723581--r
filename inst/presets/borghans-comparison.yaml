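# Bit-string contrast run: 50 pathogens x 20 peptides, near-step detection
model: bitstring
N: 100000
mu: 0.000005
generations: 2000000
seed: 1
thin: 1000
K: 1
cmax: 1.0e+12
m: 50
npep: 20
v: 7
a: 13.813509557
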