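---
title: "Simulating ancestry-assortative mating: models, calibration, and tract-based dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ancestry-assortative mating: models, calibration, and tract-based dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assortmate)
```

## The problem

In recently admixed human populations — Latino populations, African
Americans, Cabo Verdeans and others — spouses' genome-wide ancestry
proportions are positively correlated. This *ancestry-assortative mating*
is usually summarized by a single Pearson correlation between mates,
$r_{x_i,x_j}$, and then treated as if it were a fixed property of the
population. But the same correlation can be produced by very different
mechanisms: individual preferences for mates of similar ancestry, or
social-group barriers that merely happen to coincide with ancestry at the
time of admixture. Which mechanism operates matters, because assortative
mating biases downstream inference — heritability estimates, association
studies, and admixture dating from local-ancestry tract lengths.

`assortmate` provides a forward-in-time Wright–Fisher simulator of two-way
admixture under explicit mate-choice models, together with the analyses
needed to study what each mechanism does to mate correlations, ancestry
variance, mating structure, and tract-based dating.

## The simulation model

A population of $N$ hermaphroditic diploids (default $N = 10{,}000$) is
founded by a single pulse of admixture: a fraction $m$ (default $0.5$) of
founders is unadmixed from source population 1 ($x = 1$, social group A),
the rest from source 2 ($x = 0$, group B). Each generation, exactly $N$
mating events each produce one child:

* parent 1 is sampled uniformly with replacement;
* parent 2 is sampled with probability proportional to the mating weight
  $\psi_{i,j}$ of the chosen model, with selfing prohibited;
* the child receives one recombinant gamete from each parent and inherits
  parent 1's social group — group membership is *not* genetic;
* optionally, a fraction of children (default 0, or 1% in the
  continuous-migration scenario) is replaced by fresh unadmixed migrants,
  split evenly between sources. Migrants carry the source-associated group
  label and a migrant flag, and mate from the next generation onward
  (standard Wright–Fisher semantics; the alternative — migrants arriving
  before mating — would only shift the migrant bookkeeping by one
  generation).

The genome is 22 independently segregating chromosomes totalling
$L = 2.88$ Gb with a uniform recombination rate $r = 10^{-8}$ per bp per
generation, so 1 cM $\equiv$ 1 Mb and the genetic map is 28.8 Morgans.
Since only totals enter the expectations used here, the per-chromosome
lengths are a free choice; we use the GRCh38 autosome lengths rescaled to
sum to exactly 2.88 Gb, and they are configurable. Meiosis draws a
Poisson($r \times$ length) number of crossovers per chromosome, uniformly
placed, with no interference; the starting haplotype of each chromosome is
a fair coin (independent assortment). Ancestry is tracked as
source-labelled tracts (0-based, half-open, maximally merged), so no
genotypes are simulated — an individual's global ancestry proportion $x$
is the source-1 fraction of its diploid tract set.

## Mate-choice models and the common strength parameter

All models are calibrated through $\alpha$, defined from the fraction $A$
of admixed offspring in the first generation after contact:
$\alpha = 1/A - 1$. At founding, every model makes an individual $\alpha$
times more likely to take a within-source mate than a cross-source mate,
so simulations with equal $\alpha$ are exchangeable in the first
generation; their dynamics diverge afterwards. The kernels are:

| kind | weight $\psi_{i,j}$ | behaviour over time |
|---|---|---|
| `random` | $1$ | baseline ($\alpha = 1$) |
| `stationary` | $e^{-\ln(\alpha)\,\lvert x_i-x_j \rvert}$ | preference per unit $\Delta x$ fixed; as $\sigma_x^2(t)$ shrinks, everyone becomes effectively less selective |
| `increasing` | $e^{-\ln(\alpha)\,\frac{\sigma_x^2(0)}{\sigma_x^2(t)}\lvert x_i-x_j\rvert}$ | selectiveness grows as the population homogenizes, compensating for lost variance |
| `broad` | $e^{-(x_i-x_j)^2/(2\sigma^2)}$, $\sigma^2 = \frac{1}{2\ln\alpha}$ | Gaussian; indifferent among similar mates, strongly against distant ones |
| `social` | $1 - \tfrac{1}{\alpha+1}$ within group, $\tfrac{1}{\alpha+1}$ between | depends only on the inherited group label, not on $x$ |

Two numerical choices deserve comment, since the source formulations of
these kernels circulate in several inconsistent forms:

* **Increasing-preference constant.** Rescaling the exponent by the
  *current* variance alone would make the founder-generation kernel
  $e^{-\ln(\alpha)|\Delta x|/0.25}$, i.e. an endogamy:exogamy ratio of
  $\alpha^4$ at founding, breaking the first-generation equivalence that
  defines $\alpha$. We therefore scale by
  $\sigma_x^2(0)/\sigma_x^2(t)$, which equals 1 at $t = 0$ and reduces the
  kernel to the stationary one there. $\sigma_x^2(0)$ is computed from the
  realized founder population ($m(1-m)$ for a fractional split). If
  $\sigma_x^2(t) = 0$ the population is ancestry-degenerate and the kernel
  falls back to uniform weights, its limiting behaviour.
* **Broad-preference width.** We take $\sigma^2 = 1/(2\ln\alpha)$, the
  unique width for which $\psi(\Delta x = 0)/\psi(\Delta x = 1) = \alpha$
  exactly, i.e. the same founding calibration as every other kernel. The
  Gaussian normalizing constant is dropped because weights are
  renormalized at sampling. At $\alpha = 1$ the width is undefined and the
  kernel is uniform by construction.

Other conventions: `random` is only accepted with $\alpha = 1$ (the
calibration identity $A = 1/(1+\alpha)$ cannot hold otherwise);
`stationary` with $\alpha = 1$ is *bit-identical* to `random` under a
shared seed, which the test suite asserts; weights are recomputed per
mating event in a single $O(N)$ scan (no caching, since the focal $x_i$
changes every event), while the social and random kernels sample in
$O(1)$ using group index tables.

## What the statistics measure

Per generation the simulator records every mating event
($x_i, x_j, s_i, s_j$, migrant flags) and reports: the Pearson mate
correlation $r$ over the $N$ ordered events (a symmetrized version is
available as a cross-check; the ordered statistic is primary); the
population ancestry variance $\sigma_x^2(t)$ (denominator $N$); the
admixed fraction; the migrant–migrant mating fraction together with its
random-mating expectation (squared migrant fraction); and the
group–ancestry association $\bar x_A - \bar x_B$. The permutation test
permutes the parent-2 column and uses the one-sided estimator
$p = (1 + \#\{r_\pi \ge r_{\mathrm{obs}}\})/(n_\pi + 1)$, so with the
conventional 1,000 permutations an observation exceeding all permuted
values gives $p < 0.001$; a two-sided variant on $|r|$ is available.
Mating-pair densities are binned on a hexagonal lattice of pitch 0.025
ancestry units (a square grid with the same pitch is provided because it
is exactly testable), scaled so the maximum cell is 1. Bimodality of the
$x$ distribution is summarized by an interior-valley heuristic — the
maximum histogram bin in $[0.4, 0.6]$ must be under half of each flanking
mode — which is deliberately crude but deterministic.

A structural fact about the social model worth knowing when interpreting
these outputs: because children take parent 1's group, the group–ancestry
association decays deterministically in expectation as
$(\alpha/(\alpha+1))^t$ — e.g. $0.59$ at $t=4$ but only $0.07$ by $t=20$
for $\alpha = 7$. Two separated ancestry modes and the two-cluster mating
structure are therefore a transient feature of the first several
generations at these strengths; afterwards the social model keeps a
positive mate correlation through group endogamy even though the group
barely predicts ancestry any more. Our unit tests assert the two-cluster
structure in that transient window.

## Dating admixture from tract lengths

Under a single pulse $t$ generations ago with founding fraction $m$,
tract lengths are approximately exponential with decay rate
$\lambda = (t+1)\,m$ per Morgan. The package fits
$\hat\lambda = 1/\bar\ell$ (the closed-form MLE; the common alternative of
regressing on a binned histogram adds only estimator noise) and inverts
$\hat t = \hat\lambda/m - 1$, clamping negative estimates to zero with a
warning. Reference quantities at the defaults:

```{r references}
expected_mean_tract_length(20, 0.5)      # cM
expected_tract_quantile(20, 0.5, 0.95)   # cM
```

Chromosome-end tracts are *included, uncorrected* in the default fit —
the naive extraction that empirical pipelines use. At $t = 20$ on this
map the censoring bias is negligible (tracts comparable to a chromosome
length are vanishingly rare), and under random mating the estimator
recovers $t$ to within a generation; a censoring-aware MLE
(events / total length) is available via `censor_aware = TRUE` for
short-$t$ settings where end effects matter. Both-source tracts are
pooled by default (the marginals coincide at $m = 0.5$); per-source
fitting is available through `source=`.

The scientifically interesting output is the *bias*: any mechanism that
still produces a positive mate correlation at the sampling time leaves an
excess of long tracts relative to the exponential fit, dragging
$\hat\lambda$ down and making admixture look more recent than it is. The
acceptance suite asserts the sign of this bias and its monotonicity in
the retained correlation; the `tail_excess` diagnostic (observed vs
fitted 95th percentile) flags the same phenomenon per fit, with the
caveat that continuous migration produces a similar excess.

## A worked example

```{r example}
cfg <- sim_config(
  N = 2000, generations = 10, model = "social", alpha = 7,
  seed = 7, snapshot_generations = 10
)
sim <- run_simulation(cfg)
round(head(sim$summary, 4), 4)

fit <- date_admixture(sim$tracts[["10"]], m = 0.5, map = cfg$map)
fit
```

The mate correlation starts near $(\alpha-1)/(\alpha+1) = 0.75$ in the
founder generation and decays; the dating fit at $t = 10$ already
underestimates the true age because group endogamy has kept long
unbroken tracts in circulation.

## Problem sizes, reproducibility, and testing

Every stochastic routine draws from R's RNG, so `set.seed()` — or the
`(seed, replicate)` pair handed to `run_simulation()` — fully determines
a run, including the C++ generation loop. The test suite works at three
scales chosen to keep expectations sharp: exact oracles (enumeration on
populations of at most 6, closed forms, analytic identities), reduced
populations on a 2x50 Mb toy map for distributional checks, and a small
number of full-map runs ($N = 2{,}000$, 3 replicates, 20 generations) for
the qualitative orderings, with the single full-scale study condition
($N = 10{,}000$, stationary, $\alpha = 10$, 5 replicates) reserved for
the replicate-band check. Micro-fixtures (`fixture_names()`) package the
analytic checks for the command line.

## What the generator does and does not emulate

The simulator reproduces the study conditions it was built for:
hermaphroditic non-overlapping generations, a single well-mixed deme, one
admixture pulse (or constant 1% migration), neutral ancestry (offspring
number is uncorrelated with $x$, which the tests verify), and a uniform
genetic map. Passing tests therefore say nothing about sex-specific
mate choice, monogamous pair formation (mates here are resampled per
event, so one individual can parent many children), spatial or
socioeconomic structure beyond a binary label, selection on ancestry,
multi-way admixture, or real recombination-map heterogeneity — all of
which shape empirical spouse correlations. Tract extraction is exact
rather than inferred, so empirical local-ancestry-calling error is also
out of scope.
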