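---
title: "Emergent heterozygote advantage and MHC allelic diversity: models and methods"
author: "mhcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent heterozygote advantage and MHC allelic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcsim)
```

## The question and the model

MHC loci are the most polymorphic genes in vertebrates, yet classical
heterozygote-advantage (HA) theory only maintains many alleles when
genotype fitnesses are tuned by hand: all heterozygotes similarly fit, all
homozygotes similarly unfit. `mhcsim` simulates a single diploid MHC locus
in which those fitness patterns *emerge* from two biological assumptions
about host–pathogen interactions:

* **(a) Undefended pathogens are lethal.** Host condition is reduced
  *proportionally* by every imperfectly countered pathogen,
  $c = c_{\max}\prod_k \bar e_k$, so a single poor defence collapses
  condition regardless of how good the other defences are.
* **(b) Pathogens hurt weak hosts more.** Survival saturates with
  condition, $s = c/(K+c)$: above the half-saturation constant $K$ extra
  condition buys almost nothing, below it every further loss is
  catastrophic.

Alleles are co-dominant, so the genotype's per-pathogen efficiency is the
arithmetic mean of its two alleles' efficiencies — the conservative choice,
since any dominance would strengthen HA. Together (a) and (b) push evolved
populations toward a bimodal fitness structure: homozygotes sit far below
$K$ (near-lethal), while heterozygotes carrying complementary alleles sit
far above $K$, all with survival near one. That is exactly the hand-tuned
pattern of classical theory, found here by evolution itself.

Two recognition models supply the efficiencies:

* **Gaussian.** Alleles are points in the $(m-1)$-dimensional space spanned
  by $m$ fixed pathogen optima (a unit-edge regular simplex by default,
  built by `simplex_optima()`), with
  $e_k(x) = \exp(-\tfrac{v^2}{2}\lVert x - p_k\rVert^2)$. The virulence $v$
  is the inverse width of the recognition kernel. A general covariance form
  `gaussian_efficiency_general()` is available for non-isotropic kernels.
* **Bit-string.** Alleles and pathogen peptides are 16-bit strings; a
  peptide is detected with logistic probability
  $D(L) = 1/(1+e^{a(v-L)})$ of the longest position-aligned run $L$ of
  agreeing bits, and a pathogen with `npep` peptides is countered if any
  peptide is detected. The default steepness $a=\log 9$ puts detection at
  10% one match below $v$ and 90% one above.

The Wright–Fisher cycle (fixed $N$, non-overlapping generations) is:
deterministic Hardy–Weinberg proportions; viability selection by the
genotype survival table; one multinomial draw of $N$ surviving offspring
over unordered genotype categories; then per-copy mutation with
$\mathrm{Binomial}(2N,\mu)$ events, each flipping one bit (bit-string) or
adding an isotropic normal step of expected length $\delta$ (Gaussian).
Each exported operation (`hardy_weinberg_proportions()`,
`viability_selection()`, `resample_population()`, `apply_mutation()`,
`marginal_allele_fitness()`) defines the contract; `wf_simulate()` runs the
identical cycle in compiled code, which the test suite cross-checks against
the R operations and against neutral theory.

## Analytical predictions

For the Gaussian model, gradual evolution first converges on the generalist
allele $x^*$, the arithmetic mean of the pathogen optima
(`singular_point()`). Whether evolution stops there or branches into an
expanding set of coexisting alleles is decided by the spread of the optima
relative to the recognition kernels: diversification occurs iff
$\Sigma_p^2 - 2\Sigma_G^2 > 0$ (`branching_condition_general()`), where
$\Sigma_p^2$ is the population covariance of the optima (normalised by $m$,
so the unit-edge simplex gives eigenvalues exactly $1/(2m)$) and
$\Sigma_G^2$ the kernel covariance. Under full symmetry this reduces to
$v > v_c = 2\sqrt m$ (`branching_threshold_symmetric()`). The provided
matrix inequality is interpreted as "largest eigenvalue positive"
(disruptive selection in at least one direction suffices); full positive
definiteness is reported alongside, and the two coincide in the symmetric
case. Note $v_c$ *increases* with $m$: many pathogens disfavour the initial
diversification, because specialising on some means failing many.

```{r predict}
predict_branching(load_config("fig3A"))
```

## Parameters, units and defaults

| Parameter | Meaning | Typical values used here |
|---|---|---|
| `N` | diploid population size | 2e4–2e5 |
| `mu` | per-copy mutation probability per generation | 5e-7–2.5e-5 |
| `m` | number of pathogens | 3 (Gaussian demos), 12–50 (bit-string) |
| `v` | virulence (inverse kernel width / 50%-detection match length) | 2–9 |
| `K` | survival half-saturation constant (condition units) | 0.01–10 |
| `cmax` | condition of a perfectly defended host | see below |
| `delta` | expected mutational step length (trait units) | 0.016–0.03 |
| `npep` | peptides per pathogen | 1–20 |
| `a` | detection-logistic steepness | log 9 (near-step: 2·log 999) |

The mutation kernel is calibrated so the *expected step length* equals
$\delta$: per-axis $\sigma = \delta\,\Gamma(h/2)/(\sqrt2\,\Gamma((h+1)/2))$
in $h$ dimensions. Mutants are never clipped to the pathogen simplex;
selection removes outside wanderers on its own. Continuous traits mean
every Gaussian mutation founds a new allele (tracked by id); bit-string
mutants identical to a resident string merge into its allele class.

### Calibrating `cmax`

`cmax` has no default: it sets where the realised conditions fall relative
to $K$, and that placement *is* the biology of assumption (b). Only
genotypes whose condition straddles $K$ feel the saturation; if every
genotype sits far below $K$, survival is proportional to condition, $K$
cancels from relative fitness, and the characteristic $K$-dependence of
allelic diversity disappears (we verified this degenerate regime
numerically). The bundled Gaussian presets therefore use
$c_{\max} = \exp(v^2(m-1)/4)$, the value at which the generalist
homozygote's condition equals 1: specialist homozygotes then fall below
$10^{-4}$, the generalist homozygote is intermediate, and
specialist–generalist heterozygotes reach $\sim 10^4$ with survival
$\approx 1$ even at $K = 10$ — the published condition distributions. The
bit-string presets use $c_{\max} = 10^{12}$, which likewise places evolved
heterozygotes orders of magnitude above $K = 1$ and homozygotes below it.

## The synthetic pathogen communities

The generators are first-class model components, not test scaffolding.
`simplex_optima(m)` builds the maximally symmetric community — all
pathogens equidistant at distance 1, generalist exactly at the origin —
which is what makes the closed-form threshold $v_c = 2\sqrt m$ exact.
`random_pathogens(m, npep)` draws independent uniform 16-bit peptides,
reproducibly from the run seed. What these emulate is a *fixed* pathogen
community: optima and peptides never move, deliberately excluding
Red-Queen coevolution so that any polymorphism is attributable to HA alone.
Real pathogen communities are neither equidistant nor static, and real MHC
alleles mutate by more than single-bit flips; passing tests therefore
demonstrate the claimed eco-evolutionary mechanism, not quantitative
predictions for any natural system.

## Numerical choices

* Condition is accumulated in log space; survival is evaluated as
  $1/(1+\exp(\log K - \log c))$, exact and immune to underflow of the
  $m$-fold product. If every genotype's survival underflows to zero,
  selection falls back to relative weights
  $\exp(\log c - \max \log c)$ — the exact limit of normalised selection
  when all conditions are far below $K$.
* Bit-string efficiencies use `log1p`/`expm1`, so they never collapse to
  exactly 0 even with near-step steepness.
* The multinomial draw is over unordered genotype categories
  ($n(n+1)/2$ cells); allele copy-counts always sum to $2N$ and extinct
  alleles are pruned each stage.
* Mutation picks *distinct* copies (a copy mutates at most once per
  generation), so `mu = 1` mutates every copy exactly once.
* Survival tables are maintained incrementally: rows are appended for new
  alleles and compacted on extinction; bit-string efficiency vectors are
  memoised by string (only 65,536 possible alleles).
* One seed drives everything; the generation loop is re-seeded separately
  (deterministically) from the setup draws, so a run is bit-identical when
  replayed from its manifest with pathogens and founder allele resolved.
* Equilibration is by fixed generation budget, no convergence detection;
  snapshots are thinned (`thin`) plus the final generation.

## Problem sizes used in tests and the acceptance script

Closed-form checks are instant. The stochastic checks use: scaled branching
runs at $N = 2\times10^4$, $\mu = 10^{-5}$ (preserving $N\mu$),
$2\times10^5$ generations; flat-survival runs at $N=10^3$,
$\mu = 5\times10^{-5}$ over $4\times10^5$ generations, recovering
$1+4N\mu$ within sampling error; and the headline Gaussian runs at the
full published parameters ($N = 2\times10^5$, $\mu = 10^{-6}$,
$\delta = 0.016$) for $5\times10^5$ generations, which the compiled engine
completes in under a minute each. Final-snapshot effective allele numbers
are averaged over two to three seeds because the equilibrium fluctuates
(roughly ±15% at $K = 0.1$).

## Design choices where the design was open

* **Genotype-frequency representation.** The stated cycle (deterministic
  HW and selection, one multinomial draw) is exactly representable on
  genotype proportions; an individual-based implementation would add
  nothing but cost.
* **Mutation after resampling**, applied to the adult copy pool: this
  matches a per-capita recurrent-mutation reading and keeps the
  $1 + 4N\mu$ baseline exact; $\mu$ is per allele copy ($2N$ trials).
* **$n_e$ is inverse homozygosity**, reported both at the final snapshot
  (used for figure comparisons) and time-averaged (used against
  baselines); whether published values are final-snapshot or time-averaged
  is not always stated, so both are emitted.
* **Threshold allele counts** use the conventional inclusive 1% cutoff,
  configurable.
* **Condition histograms** weight genotype classes by Hardy–Weinberg
  proportions at the realised adult frequencies, with absorbing end bins
  (everything below $10^{-4}$ in the first bar, everything above $10^4$ in
  the last).
* **Package shape.** The package is organised around one main entry point,
  `wf_simulate()`, returning a classed object with `print`, `summary`,
  `plot` and `simulate` methods, in the style of classic R modelling
  packages; `coef`/`predict`/`residuals` have no meaning for a forward
  simulator and are omitted. The CLI (`inst/cli/mhcsim.R`) is a thin
  wrapper over exported functions.

## Known limitations

* **Bit-string diversity under aligned matching.** With matching defined as
  the longest *position-aligned* run of agreeing bits (as implemented and
  depicted by the match-length operation), exhaustive evaluation of all
  65,536 possible alleles against an `m = 12`, `npep = 3`, `v = 7`
  pathogen draw shows the best possible allele strongly detects only ~6 of
  12 pathogens. Sets of mutually complementary alleles are then
  combinatorially capped near three, and simulated diversity plateaus at
  $n_e \approx 2\text{–}3$ (occasionally ~8) rather than the mid-teens
  reported for this regime in the literature this model family comes from.
  Offset-tolerant matching makes detection far too easy instead (perfect
  generalist alleles exist). Published mid-teens bit-string diversity
  therefore appears to require a recognition rule intermediate between
  these extremes; the package implements the aligned rule and reports what
  it produces. The Gaussian model — where the package's analytical and
  simulation results agree quantitatively with the published values — is
  unaffected.
* Single locus only; no gene duplication, no linked variation. Gene
  conversion enters only through the closed-form baseline
  `gene_conversion_ne()`.
* The pathogen community is fixed: no Red-Queen dynamics, no virulence
  evolution, no fluctuating selection — by design, to isolate HA.
* Viability selection only; fecundity, age structure and mate choice
  (e.g. disassortative mating) are out of scope.
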