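# mhcsim

Forward-in-time simulation of a single MHC locus under viability selection,
for population geneticists and theoretical immunologists studying how
**heterozygote advantage (HA)** can generate and maintain extreme allelic
polymorphism. Genes of the major histocompatibility complex carry over 100
alleles per population; classical overdominance models only sustain such
numbers with hand-picked genotype fitnesses. Here genotype fitness *emerges*
from host–pathogen recognition, and large allele numbers can evolve by
repeated evolutionary branching.

## The model

A diploid Wright–Fisher population of fixed size `N` (non-overlapping
generations, random mating) evolves at one MHC locus:

1. **Recognition.** Each allele `x` has an efficiency `e_k(x) ∈ [0, 1]`
   against each of `m` fixed pathogens.
   * *Gaussian model*: alleles are points in the `(m−1)`-dimensional space
     spanned by pathogen optima `p_k` (a unit-edge regular simplex by
     default), with `e_k(x) = exp(−(v²/2)‖x − p_k‖²)`; the virulence `v` is
     the inverse kernel width. Mutations are isotropic normal steps with
     expected length `δ`.
   * *Bit-string model*: alleles and pathogen peptides are 16-bit strings.
     A peptide is detected with probability
     `D(L) = 1/(1 + exp[a(v − L)])`, where `L` is the longest run of
     positions on which the strings agree, and a pathogen is countered if
     any of its `npep` peptides is detected:
     `e_k = 1 − ∏_i (1 − D(L_ki))`. Mutations flip one random bit.
2. **Fitness.** Alleles are co-dominant: the genotype efficiency is the mean
   of the two allele efficiencies. Condition is multiplicative,
   `c = c_max ∏_k ē_k`, so one undefended pathogen collapses condition
   (pathogens are lethal without an adequate defence), and survival
   saturates, `s = c/(K + c)`, so pathogens harm hosts in poor condition
   far more (the half-saturation constant `K` is the condition giving 50%
   survival).
3. **Generation cycle.** Deterministic Hardy–Weinberg proportions →
   viability selection → multinomial resampling of `N` survivors →
   per-copy mutation (`Binomial(2N, μ)` events).

For the Gaussian model the package also computes the adaptive-dynamics
predictions: the singular "generalist" allele `x*` (mean of the optima) and
the evolutionary branching condition `Σ_p² − 2Σ_G² > 0`, which under full
symmetry reduces to `v > 2√m`.

Diversity is summarised by the effective number of alleles `n_e = 1/Σq_i²`
(inverse homozygosity), allele counts above 1% frequency, and the
mutation-drift (`1 + 4Nμ`) and gene-conversion (`1 + 4rN_e`) baselines.

## Worked example

```r
library(mhcsim)

cfg <- load_config("fig3C")   # Gaussian, m = 3, v = 7, K = 0.1, N = 2e5
cfg$generations <- 5e5L
sim <- wf_simulate(cfg, record_alleles = FALSE)
print(sim)
#> Wright-Fisher MHC simulation (gaussian model)
#>   N = 200000, mu = 1e-06, 500000 generations, seed 1
#>   m = 3 pathogens, v = 7, K = 0.1, cmax = 4.36732e+10, delta = 0.016
#> Final generation: 29 alleles, 22 at >= 1% frequency, ne = 18.66

predict_branching(cfg)
#> Evolutionary branching verdict at the generalist allele
#>   singular point x*: 0, 2.082e-17
#>   eigenvalues of Sigma_p^2 - 2 Sigma_G^2: 0.1259, 0.1259
#>   branching: TRUE (positive definite: TRUE)
```

The run starts from the generalist allele, branches repeatedly (branching is
predicted since `v = 7 > 2√3 ≈ 3.46`), and fluctuates around an effective
allele number in the mid-teens — an order of magnitude above the
mutation-drift baseline `1 + 4Nμ = 1.8`. `summary(sim)` adds the time-averaged `n_e` and
homozygosity; `plot(sim)` shows the diversity trajectory and the final
condition histogram split into homozygotes (low condition, near-lethal) and
heterozygotes (condition far above `K`, survival near 1) — the emergent
fitness structure that lets many alleles coexist.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/mhcsim.R simulate fig3C out/   # trajectory.tsv, manifest.json, ...
Rscript inst/cli/mhcsim.R predict fig3A
Rscript inst/cli/mhcsim.R sweep inst/presets/fig4-slice.yaml sweep.tsv
```

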