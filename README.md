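# assortmate

Forward-in-time simulation of **ancestry-assortative mating** in admixed
populations, with the downstream analyses used to interpret it.

In several recently admixed human populations, spouses' genome-wide
ancestry proportions are positively correlated. That single observed
correlation, r<sub>x_i,x_j</sub>, is compatible with very different
mechanisms — individual preferences for ancestry-similar mates, or social
group barriers that merely coincided with ancestry when admixture began —
and the mechanism matters because assortative mating biases admixture
dating, heritability estimation, and association studies. `assortmate`
lets you simulate each mechanism explicitly and measure what it does to
mate correlations, ancestry variance, mating structure, and
local-ancestry tract lengths.

## The models

A Wright–Fisher population of N hermaphroditic diploids (default
N = 10,000) is founded by a single admixture pulse: a fraction m (default
0.5) of founders from source 1 (x = 1, group A), the rest from source 2
(x = 0, group B). Each generation, N mating events each produce one
child: parent 1 is sampled uniformly, parent 2 proportionally to a mating
weight ψ<sub>i,j</sub>, selfing excluded; children inherit parent 1's
social group. The genome is 22 chromosomes totalling 2.88 Gb with uniform
recombination r = 1e-8/bp (28.8 Morgans; 1 cM = 1 Mb), and ancestry is
propagated as source-labelled tracts through Poisson-crossover meiosis —
no genotypes are simulated.

All mate-choice models share a strength parameter α, defined so the
first-generation admixed-offspring fraction is A = 1/(1+α):

| kind | ψ(i, j) |
|---|---|
| `random` | 1 |
| `stationary` | exp(−ln(α)·\|x_i − x_j\|) |
| `increasing` | exp(−ln(α)·(σ²ₓ(0)/σ²ₓ(t))·\|x_i − x_j\|) |
| `broad` | exp(−(x_i − x_j)²/(2σ²)), σ² = 1/(2·ln α) |
| `social` | 1 − 1/(α+1) within group, 1/(α+1) between |

Tract-based dating fits the exponential tract-length model
λ = (t+1)·m (per Morgan) by maximum likelihood and inverts it to
t̂ = λ̂/m − 1; mechanisms that keep mating assortative leave an excess of
long tracts and bias t̂ downward.

## A worked example

Ten generations under a social-group barrier with α = 7:

```r
library(assortmate)
cfg <- sim_config(N = 2000, generations = 10, model = "social", alpha = 7,
                  seed = 7, snapshot_generations = 10)
sim <- run_simulation(cfg)
round(head(sim$summary, 4), 4)
#>   t      r sigma2 admixed_fraction migrant_mating_fraction group_assoc
#> 1 1 0.7588 0.2196           0.1205                       0      0.8793
#> 2 2 0.6518 0.1816           0.3295                       0      0.7698
#> 3 3 0.6115 0.1476           0.6040                       0      0.6728
#> 4 4 0.6041 0.1194           0.8605                       0      0.5970
```

The founder-generation mate correlation starts at
(α−1)/(α+1) ≈ 0.75 and decays as the population mixes; `sigma2` is the
ancestry variance σ²ₓ(t), `admixed_fraction` starts at
1/(1+α) = 0.125, and `group_assoc` (mean x difference between groups)
decays as (α/(α+1))^t because group labels are inherited socially, not
genetically. The correlation is still highly significant at t = 10:

```r
permutation_test(sim$records[sim$records$t == 10, ], n_perm = 1000)$p_value
#> [1] 0.000999001
```

Dating the pulse from the generation-10 tract table shows the bias that
assortative mating induces:

```r
date_admixture(sim$tracts[["10"]], m = 0.5, map = cfg$map)
#> <exponential_fit> lambda_hat=3.819 /M  t_hat=6.64 generations (m=0.5)
#>   mean=26.18 cM  q95=83.59 cM  tail excess=5.15 cM  (n=439980 tracts)
```

The true age is 10 generations; persistent endogamy keeps long tracts in
circulation (positive tail excess over the exponential fit) and makes
admixture look 3–4 generations too recent.

A thin command-line front end is installed with the package
(`system.file("cli", "assortmate", package = "assortmate")`) with
`simulate`, `date-admixture` and `fixtures` subcommands over YAML
configs and BED-like tract tables. See the vignette
(`vignettes/ancestry-assortative-mating.Rmd`) for the full model
description and design choices.

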