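---
title: "Negative autoregulation in diploids: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative autoregulation in diploids: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diplonar)
```

# The model

A negatively autoregulating transcription factor represses its own
transcription. In a haploid cell the amount of repression a gene experiences
depends only on its own output; in a diploid, two homologous copies share
one protein pool, so each allele is repressed by the *combined* output of
both. `diplonar` models this cross-talk explicitly. For alleles
$i = 1, \dots, n$ (ploidy $n \in \{1, 2\}$):

$$
\frac{dm_i}{dt} = \beta_b + \beta_r\, f(P; K_i, h_i) - \delta_m m_i,
\qquad
\frac{dp_i}{dt} = \alpha\, m_i - \delta_p p_i,
\qquad
P = \sum_i p_i,
$$

with the Hill repression function

$$
f(P; K, h) = \frac{1}{1 + (P/K)^h}.
$$

Transcription runs at the background rate $\beta_b$ plus a regulated
increment $\beta_r f(P)$, so the maximal rate is
$\beta_{\max} = \beta_b + \beta_r$ (no repressor, $f = 1$) and the minimum
is $\beta_b$ ($f \to 0$). This split is the only decomposition consistent
with both limits: an unregulated gene transcribes at $\beta_{\max}$, a fully
repressed one at $\beta_b$. $K_i$ is the dissociation constant of allele
$i$'s autoregulatory binding site (smaller $K$ = stronger binding), and
$h_i$ its Hill coefficient ($h = 1$ for a single binding site, the case of
primary interest; $h > 1$ stands in for cooperative or multiple sites).

Assumptions worth keeping in mind:

* repression is the quasi-equilibrium Hill form — promoter (bound/unbound)
  state is not modelled explicitly;
* both alleles read the same nuclear protein pool instantaneously;
* only intrinsic noise is modelled in the stochastic module — no extrinsic
  or ON/OFF input noise, no cell division or partitioning.

# Parameters

The model is dimensionless; `default_params()` fixes the reference
conditions used throughout the package:

| parameter | default | meaning |
|---|---|---|
| $\delta_p$ | 1 | protein decay; sets the time unit (one protein lifetime) |
| $\delta_m$ | 10 | mRNA decay; ten-fold timescale separation, as assumed by the quasi-steady-state analysis |
| $\alpha$ | 100 | translation rate; burst size $\alpha/\delta_m = 10$, typical for transcription factors |
| $\beta_r$ | so the unregulated diploid equilibrium is 1000 proteins | sets the copy-number scale shared by the ODE and stochastic modules |
| $b = \beta_b/\beta_r$ | $10^{-3}$ | background-to-regulated transcription ratio |

Concentrations are molecule-number-scaled, so the deterministic and
stochastic modules share the same parameter values. All defaults are
overridable (`default_params()` arguments, or a YAML configuration via
`load_config()`).

Under these conditions the small-perturbation optimal binding strength is
$K_{\mathrm{opt}} \approx 1$ (in protein-number units) with optimal
equilibrium $P_{\mathrm{opt}} \approx 32$ — regulated expression sits at a
few percent of the unregulated level, as expected for a strongly
self-limiting repressor.

# Response time

The response time of a genotype is the time to return to its *own*
equilibrium after a perturbation that scales protein (and by default mRNA)
to a fraction $\gamma$ of equilibrium. We measure the **last exit from the
recovery band** $|P(t) - P_{\mathrm{eq}}| \le (1-\theta) P_{\mathrm{eq}}$
(default $\theta = 0.9$). For the typical monotone recovery this is exactly
the first upward crossing of $\theta P_{\mathrm{eq}}$; for strongly binding
genotypes, whose recovery overshoots before settling, it additionally
charges the decay of the overshoot. A plain first-crossing rule would make
response time *monotonically decreasing* in binding strength — strong
binders reach 90% of their (much lower) equilibrium almost immediately —
and over-regulation would never be penalised; the band definition is what
makes "overshooting the optimum" a measurable cost, which both the
homozygote invasibility analysis and the adaptive walks rely on.

Two properties of the default ($b = 10^{-3}$) conditions deserve explicit
mention because they are easy to mistake for bugs:

* **The full-perturbation optimum is stronger than the eigenvalue optimum.**
  Minimising the measured $\gamma = 0$ response time over $K$ gives
  $K \approx 0.024\,K_{\mathrm{opt}}$ (see
  `analysis/01_optimal_binding.R`). Large perturbations reward the fast
  unrepressed rise toward a low equilibrium far more than the local
  relaxation rate does, and the gap widens as $b$ decreases. The two
  optima converge for larger background rates.
* **Response time is not monotone in $\gamma$ at strong binding.** Near
  $K_{\mathrm{opt}}$ a full knock-down recovers in 0.44 lifetimes while a
  perturbation to 30% of equilibrium needs 0.73: at low protein the
  promoter is fully derepressed and transcribes maximally (the classic
  autoregulatory burst), while at intermediate levels it is already
  repressed. In the weak-binding regime the scan is monotone, matching the
  linear-cascade intuition.

Numerically, response times come from a compiled adaptive Dormand–Prince
5(4) integrator (relative tolerance $10^{-8}$, absolute tolerances scaled
to the equilibrium state, maximum step $0.02/\delta_p$) with band crossings
located on cubic Hermite interpolants of accepted steps; a trajectory must
stay inside the band for $12/\delta_p$ before it counts as settled, and a
horizon of $80/\delta_p$ (configurable) bounds the search. The test suite
cross-validates this path against an independent `deSolve` (LSODA)
implementation to about $10^{-7}$ relative and against the closed-form
solution of the unregulated linear cascade.

# Quasi-steady-state reduction and eigenvalues

With $\delta_m \gg \delta_p$, mRNA equilibrates quickly and the model
reduces to protein-only dynamics

$$
\frac{dp_i}{dt} = c\,(b + f(P; K_i, h_i)) - \delta_p p_i,
\qquad c = \frac{\alpha \beta_r}{\delta_m}.
$$

The reduction is exact at fixed points and accurate for the slow dynamics
(response times agree with the full model to within 5% at
$\delta_m/\delta_p = 100$; `qss_reduce()` warns when the separation is
violated). Linearising at equilibrium gives the relaxation rates:

* homozygote (all alleles $(K, h)$):
  $\lambda = -\delta_p + n\,c\,f'(P_{\mathrm{eq}})$;
* heterozygote: the $2 \times 2$ Jacobian has eigenvalues $-\delta_p$
  (the allelic-difference mode $p_1 - p_2$, which carries no total protein
  and is invisible to recovery of $P$) and
  $\lambda = -\delta_p + c\,(f_1' + f_2')$, the mode on which the total
  relaxes. `lyapunov_heterozygote()` returns the latter; the test suite
  checks it against a numerical eigen-decomposition (selecting the
  eigenvector with non-zero component sum) and against log-linear decay
  fits of small perturbations.

Because $f' \le 0$, every $\lambda \le -\delta_p$: autoregulation can only
speed relaxation. $|\lambda|$ is maximised at $K_{\mathrm{opt}}$; for
$h = 1$ the maximiser satisfies the closed form
$P_{\mathrm{eq}}/K = \sqrt{1 + 1/b}$, which the test suite uses as a
calculus oracle for the golden-section search in `optimal_Kd()`
(tolerance $10^{-10}$ on $\log K$).

**Under-dominance decomposition.** For a heterozygote with shared $h$,
`decompose_heterozygote()` compares $\lambda_{\mathrm{het}}$ with the
homozygote-form system matched to the *same* equilibrium total protein
(its $K$ obtained by monotone inversion of the equilibrium map). On
magnitudes,

$$
|\lambda_{\mathrm{het}}|
 = |\lambda_{\mathrm{hom}}(P_{\mathrm{het}})| - \text{correction},
\qquad \text{correction} \ge 0,
$$

with equality iff the alleles are identical. Both eigenvalues are negative
numbers; the package stores them signed and defines
$\text{correction} = \lambda_{\mathrm{het}} - \lambda_{\mathrm{hom}}$,
which is the only sign convention under which the penalty is non-negative
while the heterozygote is the slower system. The correction vanishes with
the squared allelic expression difference
$\Delta^2 = (p_{1,\mathrm{eq}} - p_{2,\mathrm{eq}})^2$ (computed from the
reduced equilibrium, i.e. protein concentrations) and grows monotonically
with allelic divergence at fixed geometric-mean binding. Rather than
hard-coding a closed form for the correction, the package *defines* it by
the reconstruction identity and verifies the structural claims
(non-negativity, zero at $\Delta^2 = 0$, monotone growth) — for shared $h$
the non-negativity follows from concavity of $f(1-f)$, so this is a
theorem about the model, not a numerical accident.

# Stochastic simulation and the linear-noise companion

The intrinsic-noise module simulates the integer-count birth–death scheme
(per allele: transcription at $\beta_b + \beta_r f(P)$ with $P$ the total
protein *count*, mRNA decay, translation, protein decay) with the exact
direct-method SSA in compiled code. Tau-leaping is deliberately avoided:
copy numbers are small enough that exactness is cheap, and Fano-factor
estimates need it. Stationary moments are time-averages (states weighted by
their waiting times) over a window after burn-in, averaged across
replicates, with standard errors from replicate scatter; a first-half vs
full-window drift check warns about non-stationarity. Every replicate draws
its own RNG stream from the master seed via `derive_seeds()`, so runs are
bit-reproducible and order-independent.

Two finite-copy-number facts shape the tests:

* the *stationary mean* exceeds the deterministic equilibrium at strong
  binding (+25% at $0.1\,K_{\mathrm{opt}}$, +2% at $10\,K_{\mathrm{opt}}$,
  <1% above $30\,K_{\mathrm{opt}}$, measured): mean-field agreement is an
  asymptotic, large-copy-number statement and is tested as such;
* the unregulated gene obeys the classical two-stage result
  $\mathrm{Fano}(P) = 1 + \alpha/(\delta_m + \delta_p) \approx 10.1$ and
  Poisson mRNA, which anchor the simulator against closed forms.

`lna_moments()` provides a deterministic companion: the stationary
covariance of the linearised fluctuations from the Lyapunov equation
$A\Sigma + \Sigma A^\top + B = 0$, with $A$ the model Jacobian and $B$ the
diagonal matrix of birth and death fluxes. It is exact for the unregulated
gene and carries an $O(1/P_{\mathrm{eq}})$ bias otherwise (about 3% on the
Fano factor at $P_{\mathrm{eq}} \approx 32$, shrinking with copy number).
Its purpose is resolution: the heterozygote-vs-homozygote Fano difference
for a 1-kT mutation is *sub-percent* near its sign change, far below what
Monte-Carlo sampling can resolve in any reasonable compute budget (a 0.1%
standard error needs on the order of $10^9$–$10^{10}$ events per grid
point). `noise_selection_landscape()` therefore locates the noise-optimal
binding strength and the under-dominance thresholds on the LNA curves by
root-finding, while the test suite separately validates the LNA against
the exact simulator at the precision the SSA can deliver (means within a
few percent, Fano within 10%, plus sign checks on the strong-signal
homozygote changes). Under the default conditions the noise-optimal
binding coincides with $K_{\mathrm{opt}}$ and the heterozygote threshold
sits 10.8-fold weaker — the "order of magnitude" gap between what noise
selection would favour and what heterozygotes allow.

# Binding-site evolution

The evolutionary module uses the standard additive mismatch energy model:
a site of $L$ positions, each contributing $\varepsilon_i$ (kT) to the
binding energy when matched to its optimal base and 0 otherwise, with
$K = K_0 e^{-E}$. Generator defaults, chosen once as the study conditions:

* **length distribution**: discrete on 5–22 nucleotides with mode near 10
  and mean 10 (a truncated shifted Poisson), standing in for the empirical
  length distribution of eukaryotic transcription-factor motifs; a user
  may substitute an empirical histogram;
* **energies**: $\varepsilon_i \sim U(0.05, 3)$ kT — covering the
  empirically estimated 1–3 kT per-nucleotide range while keeping
  small-effect mutations frequent, so gradualist paths to strong binding
  exist;
* **$K_0 = 10^3 K_{\mathrm{opt}}$**: the fully mismatched site is
  effectively unregulated;
* **exclusion**: sites whose fully matched sequence is still weaker than
  $K_{\mathrm{opt}}$ are redrawn (counted), since they could never reach
  the fast-response regime.

An adaptive walk starts fully mismatched and proposes uniformly random
mismatch-to-match flips (back-mutations never occur). A flip fixes when the
carrier's measured response time is at most the resident's
($t_{\mathrm{mut}} \le t_{\mathrm{res}}(1 + 10^{-9})$, the tie tolerance
implementing "less than or equal" with floating-point safety): haploid
carriers are evaluated as haploids, diploid carriers in the *heterozygote*
state against the resident homozygote, and an accepted mutant becomes the
new homozygous resident. A rejected flip is not re-proposed against the
same resident; rejection marks are cleared on every acceptance because a
new background can revalue old rejections — this makes termination
("no improving flip remains") exact. Ensembles are paired: each replicate
draws one site and one proposal-order seed shared by both ploidies, so
ploidy is the *only* difference, and a control mode evaluating diploid
mutants as homozygotes reproduces (exactly, decision by decision) a
doubled-rate haploid — demonstrating that the heterozygote step, not
diploidy per se, is the constraint.

Outcome under the default conditions (240 paired replicates): haploids
descend to the strongest useful binding — the direct-protocol optimum,
$\approx 0.013$ in absolute units — while diploids stall near
$K_{\mathrm{opt}}$, a geometric-mean ratio of roughly 60–80 (seed-dependent),
i.e. diploid binding evolves about two orders of magnitude weaker. The
separation is emergent: no step of the walk encodes ploidy beyond the
fitness evaluation.

# Synthetic census

`generate_census_table()` builds signed regulator→target edge lists with
the structure of curated regulatory-network tables: each factor negatively
or positively autoregulates with set probabilities (mutually exclusive
self-edge), and repressive function overall occurs at a set rate, with
negative autoregulators counting as repressors by construction (their
self-edge represses). `census()` counts: negative autoregulator = self-edge
with sign repression or dual; repressor = at least one repression/dual edge
to any target (self included); "dual" counts toward both classifications.
Duplicate edges collapse with sign reconciliation
(repression + activation → dual). Fractions are reported exactly; rounding
is left to presentation. These counting semantics are deliberately explicit
and configurable because curation conventions differ between databases; the
generator is a synthetic stand-in, not a substitute for curated tables,
which can be supplied in the same three-column TSV schema.

# Problem sizes and reproducibility

The scales used by the shipped analyses and tests, chosen to give stable
estimates at interactive runtimes on a single core:

* invasibility grids: 40 resident binding strengths
  ($[10^{-2}, 10^2] \times K_{\mathrm{opt}}$, log-spaced) × 50 mutation
  sizes (0.05–5 kT) in both carrier modes (≈ 10 s);
* evolution: 240 paired replicates per ploidy (≈ 10–15 s), standard errors
  on the log geometric-mean ratio around 0.13;
* stationary moments: 6–8 replicates × 300–800 protein lifetimes per
  genotype (Fano standard errors 1.5–3%);
* decomposition property checks: 100 random parameter draws.

All randomness flows from explicit seeds; `run_experiment()` writes a
provenance record (configuration echo, seed, package version) next to
every output.

# Limitations

* The model omits promoter-state dynamics, extrinsic noise, chromatin or
  post-translational regulation, and population genetics (drift, fixation
  probabilities): "favoured" means the deterministic response-time or
  noise comparison.
* Only pairwise resident/mutant comparisons are implemented; multi-member
  allele sets and multiple discrete weak binding sites are outside scope
  (steeper Hill coefficients serve as the effective-cooperativity probe).
* The binding-site alphabet is match/mismatch, not four letters; this is
  the standard simplification of the mismatch energy model.
* Quantities tied to the redacted details of real regulatory data — the
  empirical motif-length histogram, database curation rules — use
  documented synthetic stand-ins; conclusions about real networks should
  use user-supplied tables where available.
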