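# Gaussian model, three pathogens, v = 7, K = 0.01
model: gaussian
N: 200000
mu: 0.000001
generations: 1000000
seed: 1
thin: 1000
K: 0.01
cmax: 4.3673179098e+10
m: 3
v: 7
delta: 0.016
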