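# Flat-survival (mutation-drift) baseline run
model: neutral
N: 100000
mu: 0.0000005
generations: 1000000
seed: 1
thin: 1000
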