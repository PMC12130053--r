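# befpart

Additive partitioning of biodiversity effects for factorial greenhouse
experiments.

`befpart` is for ecologists running (or simulating) diversity–ecosystem
function experiments in which plant communities of varying species richness
are grown under crossed soil treatments — here, drought and biochar
amendment — and the question is whether mixtures outperform the expectation
set by their members' monocultures, and *why*. The package covers the whole
computational path: balanced factorial design construction, functional-trait
computation from individual-level morphometrics, the additive partition of
the net biodiversity effect, grouped summaries with bootstrap uncertainty,
and tidy exports for external mixed-model fitting. A synthetic-experiment
generator with exported ground truth makes every stage testable against
known answers.

## The partition

For a mixture of `N` species with observed per-species yields `Y_i` and
monoculture baseline yields `M_i` (the mean biomass of species `i` grown
alone under the same treatment), define the relative yields and their
deviations from the naive expectation `1/N`:

    RY_i  = Y_i / M_i
    ΔRY_i = RY_i − 1/N

The net biodiversity effect and its two additive components are

    NBE = Σ Y_i − Σ p_i M_i          (expected biomass uses p_i = 1/N)
    CE  = N · mean(ΔRY) · mean(M)    (complementarity effect)
    SE  = N · cov(ΔRY, M)            (selection effect; population covariance)

With planting proportions `p_i = 1/N` and the population covariance
(denominator `N`), the identity `NBE = CE + SE` is exact. `befpart` treats
that identity as a *certificate*: every partition recomputes the residual
and raises a diagnostic error if it exceeds `1e-9 · max(1, |NBE|)`. CE > 0
indicates average overyielding (niche differentiation or facilitation);
SE ≠ 0 indicates that species with particular monoculture yields dominate
the mixture response — positive when high-yielding species dominate,
negative when subordinate, low-yielding species overperform.

## Worked example

A two-species mixture with monoculture baselines 10 g and 20 g produced
8 g of each species:

```r
library(befpart)
r <- partition_mixture(Y = c(8, 8), M = c(10, 20))
unlist(r[c("observed", "expected", "nbe", "ce", "se")])
#> observed expected      nbe       ce       se
#>       16       15        1        3       -2
r$species
#> # A tibble: 2 × 6
#>   species   Y_g   M_g     p    ry   dry
#>   <chr>   <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 sp1         8    10   0.5   0.8   0.3
#> 2 sp2         8    20   0.5   0.4  -0.1
```

The mixture beat its expectation by 1 g (NBE). Both species overyield on
average (CE = 3 g), but the *weak* species (baseline 10 g) overperforms
while the strong one underperforms, so selection is negative (SE = −2 g)
and NBE = CE + SE exactly.

The same partition applied to a full simulated experiment — 5 species,
richness levels {1, 2, 4}, four treatments, five replicate communities,
60 pots — and summarised per cell:

```r
cfg  <- generator_config(seed = 42)
sim  <- generate_experiment(cfg)
agg  <- aggregate_pots(sim$individuals, sim$design)
part <- partition_dataset(agg, sim$design)
group_summary(part$results, keys = c("richness", "drought", "biochar"),
              variable = "ce_g", seed = 42)
#> # A tibble: 8 × 9
#>   richness drought biochar variable     n  mean    sd ci_lower ci_upper
#>      <int>   <int>   <int> <chr>    <int> <dbl> <dbl>    <dbl>    <dbl>
#> 1        2       0       0 ce_g         5 0.565 0.683   -0.174     1.34
#> 2        2       0       1 ce_g         5 0.960 1.47    -0.722     2.34
#> 3        2       1       0 ce_g         5 0.549 0.842   -0.453     1.31
#> 4        2       1       1 ce_g         5 1.72  1.94    -0.189     4.28
#> 5        4       0       0 ce_g         5 1.90  0.577    1.50      2.70
#> 6        4       0       1 ce_g         5 3.44  1.53     1.58      4.80
#> 7        4       1       0 ce_g         5 1.48  0.548    0.796     1.95
#> 8        4       1       1 ce_g         5 2.09  1.20     0.952     3.57
```

Complementarity is positive throughout, grows with richness, and is largest
under biochar — the pattern the generator's defaults encode (overyielding
multipliers γ(2) = 1.15, γ(4) = 1.30, with a negative dominance skew that
keeps selection effects negative). `recovery_report(sim$truth,
part$results)` compares every cell's mean estimate against the generator's
injected truth, with Monte-Carlo standard errors.

`run_pipeline()` chains all stages from one YAML/JSON (or list)
configuration and writes headered CSV artifacts; `inst/cli/befpart.R` is a
thin command-line wrapper with subcommands `design`, `simulate`, `traits`,
`partition`, `summarize`, `run` and `validate`.

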