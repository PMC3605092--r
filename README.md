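# diplonar

Why do bacteria negatively autoregulate half of their transcription factors
while yeast, flies and humans almost never do? `diplonar` implements a
quantitative answer: in a diploid cell the two alleles of an autoregulating
gene repress each other through their shared protein pool, and this
cross-talk makes mutations that strengthen autoregulation **under-dominant**
— beneficial in homozygotes, deleterious in the heterozygotes through which
every new mutation must pass. The package is an analysis workflow for
systems biologists and evolutionary geneticists studying the negative
autoregulation (NAR) motif, ploidy effects in gene networks, and
binding-site evolution.

## The model

For alleles *i* = 1, …, *n* (ploidy *n* ∈ {1, 2}) with shared total protein
*P* = Σ *p<sub>i</sub>*:

```
dm_i/dt = beta_b + beta_r * f(P; K_i, h_i) - delta_m * m_i
dp_i/dt = alpha * m_i - delta_p * p_i
f(P; K, h) = 1 / (1 + (P/K)^h)
```

Around this two-allele ODE core the package provides:

* **response-time experiments** — perturbation/recovery integration
  (compiled adaptive RK45), per-allele recovery times, and
  mutant-invasibility grids over resident binding strength × mutation size;
* **quasi-steady-state eigenvalue analysis** — relaxation rates
  λ = −δ<sub>p</sub> + c·Σf′, the optimal binding strength
  K<sub>opt</sub>, and the under-dominance decomposition
  |λ<sub>het</sub>| = |λ<sub>hom</sub>(P<sub>het</sub>)| − correction, with
  correction ≥ 0 growing with the squared allelic expression difference Δ²;
* **intrinsic noise** — an exact (direct-method) stochastic simulator for
  the integer-count birth–death scheme, stationary Fano factors, noise
  under-dominance thresholds (with a linear-noise companion for sub-percent
  resolution), and stochastic response times;
* **binding-site evolution** — adaptive walks under the additive mismatch
  energy model (K = K₀·e<sup>−E</sup>), paired haploid/diploid ensembles in
  which ploidy is the only difference;
* **autoregulation census** — synthetic signed regulator→target tables and
  the motif-counting logic (fractions over all factors and over repressors
  only).

## Worked example

```r
library(diplonar)

params <- default_params()          # delta_p = 1 (time unit), delta_m = 10,
                                    # alpha = 100, unregulated diploid
                                    # equilibrium = 1000 proteins
red   <- qss_reduce(params, homozygote(1))
K_opt <- optimal_Kd(red, 1)
K_opt
#> [1] 0.9990009

# a 2.5-kT mutation arising on a weak-binding resident (10 x K_opt):
K_res <- 10 * K_opt
K_mut <- K_res * exp(-2.5)
response_time(homozygote(K_res), params)       # resident homozygote
#> [1] 0.6656348
response_time(homozygote(K_mut), params)       # mutant homozygote: faster
#> [1] 0.4209388
response_time(heterozygote(K_res, K_mut), params)  # the carrier: slower!
#> [1] 0.6929972

decompose_heterozygote(K_res, K_mut, 1, red)
#> <nar_decomposition> lambda_het = -1.87138, lambda_hom_matched = -1.918
#>   correction = 0.0466167, delta_sq = 3239.09 (P_het = 69.553)
```

The mutant would speed recovery as a homozygote (0.42 vs 0.67 protein
lifetimes) yet slows it in the heterozygote it actually arises in (0.69) —
under-dominance. The decomposition shows why: at matched expression the
heterozygote relaxes more slowly by an amount (0.047 per lifetime) driven
by the squared difference in allelic expression (Δ² ≈ 3239).

At evolutionary scale (paired adaptive walks, 240 replicates per ploidy):

```r
ens <- evolve_ensemble(evolution_config(n_replicates = 240, seed = 2024), params)
ens$summary$geometric_mean_K
#>          1          2
#> 0.01408195 1.08780297          # haploid vs diploid final K
ens$summary$ratio_diploid_haploid
#> [1] 77.24801
```

Haploids evolve binding near the strongest useful strength while diploids
stall roughly two orders of magnitude weaker — the quantitative signature
of the constraint.

The numbered scripts under `analysis/` run the full study (optimal binding
and decomposition, invasibility grids, allele-level dynamics, evolution
ensembles, noise landscapes, synthetic census) and write their tables under
`results/`.

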