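---
title: "Partitioning biodiversity effects in factorial greenhouse experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning biodiversity effects in factorial greenhouse experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(befpart)
```

## The scientific problem

Biodiversity–ecosystem function (BEF) experiments ask whether plant
mixtures produce more biomass than one would expect from their component
species grown alone, and whether that surplus comes from *complementarity*
(many species overyielding together, through niche differentiation or
facilitation) or *selection* (particular species — usually those with high
monoculture yields — dominating the mixture). `befpart` implements this
analysis for a greenhouse design in which communities of 1, 2 or 4 species
drawn from a 5-species pool are grown under four crossed treatments
(control, drought, biochar amendment, biochar + drought) with five
replicate communities per richness level, 60 pots in all.

## The additive partition

For a mixture of $N$ species with observed per-species yields $Y_i$ and
treatment-matched monoculture means $M_i$:

$$\mathrm{RY}_i = Y_i / M_i, \qquad
  \Delta \mathrm{RY}_i = \mathrm{RY}_i - 1/N$$

$$\mathrm{NBE} = \sum_i Y_i - \sum_i p_i M_i, \qquad
  \mathrm{CE} = N \, \overline{\Delta \mathrm{RY}} \, \overline{M}, \qquad
  \mathrm{SE} = N \, \mathrm{cov}(\Delta \mathrm{RY}, M)$$

Two conventions are fixed here, and both deserve justification because the
partition literature leaves room for ambiguity:

* **Covariance denominator.** The covariance is the *population* covariance
  (denominator $N$). This is not a stylistic choice: expanding
  $\mathrm{CE} + \mathrm{SE}$ term-by-term,
  $\sum_i \Delta\mathrm{RY}_i \overline{M} +
   \sum_i \Delta\mathrm{RY}_i (M_i - \overline{M}) =
   \sum_i \Delta\mathrm{RY}_i M_i = \sum_i Y_i - \sum_i M_i/N$,
  which equals NBE exactly when $p_i = 1/N$. With the sample covariance
  (denominator $N-1$) the identity fails. `partition_mixture()` recomputes
  the residual $\mathrm{NBE} - (\mathrm{CE} + \mathrm{SE})$ on every call
  and raises a diagnostic error if it exceeds
  $10^{-9}\max(1, |\mathrm{NBE}|)$ — a *certificate* rather than an
  assumption, so an implementation regression cannot pass silently.

* **Expected proportions $p_i$.** The deviation $\Delta\mathrm{RY}_i$
  measures against an expected relative yield of $1/N$, which presumes
  even planting — true of this design, where every pot receives four
  seedlings split as evenly as possible among its species. The default is
  therefore `proportions = "planted"` ($p_i = 1/N$), which is also the only
  choice preserving the additivity identity. Because one can also read the
  expectation as the *realized* relative abundances,
  `proportions = "observed"` weights the expected biomass by observed
  shares $Y_i / \sum_j Y_j$ instead; CE and SE are unchanged, NBE shifts,
  and the certificate is disabled (the identity genuinely does not hold in
  that mode). The ambiguity is documented rather than resolved.

Other partition conventions:

* **Baselines are treatment-matched** (`baseline = "matched"`): a drought
  mixture is compared against drought monocultures, because the partition
  is interpreted within treatments. `baseline = "control"` is available for
  sensitivity analysis against unstressed baselines.
* **Partition granularity is the pot.** Each mixture pot is partitioned
  separately against the monoculture *means* of its treatment, then
  summarised across the five replicate communities; the pot is the
  experiment's replicate unit.
* **Species death in mixture** ($Y_i = 0$) is a valid observation
  ($\mathrm{RY}_i = 0$); a mixture pot with *no* surviving biomass is
  skipped with a logged reason, as are mixtures lacking a monoculture
  baseline. Monocultures are excluded by construction ($N = 1$ leaves
  nothing to partition).
* **"Biomass" is shoot + root dry mass** summed per species per pot
  (`biomass = "total"`). Root mass is measured anyway for the
  root-to-shoot ratio, and total biomass is the self-consistent yield
  notion; `biomass = "aboveground"` restricts to shoot mass for
  comparability with studies that only harvest aboveground.

## Design construction

Mixtures are drawn by rejection sampling: the species pool is concatenated
enough times to fill `count × richness` slots (plus a random partial copy
when the slot count is not a multiple of the pool size), shuffled, and cut
into richness-sized communities; a draw is accepted when every community
has distinct members and all communities are distinct. Occurrence balance
(spread ≤ 1, exact equality when `count × richness` divides the pool size)
is automatic under this scheme, which is why it was chosen over per-subset
rejection. The retry cap (10,000) turns a genuinely infeasible request into
an explicit error rather than a hang. Within a richness level the same
communities are reused across all four treatments — the crossed design that
diversity × treatment contrasts require — and the replicate index labels
the community. Exact (≤ 1 spread) balance is enforced as the stricter
reading of "equal representation"; approximate balance would admit designs
the validator cannot distinguish from typos.

## The synthetic generator

`generate_experiment()` emulates the statistical structure the analysis
assumes, not plant physiology. Species-level pot yield is

$$Y_i = \tfrac{1}{N}\,\mu_i\, d^{\,\mathrm{drought}}\, b^{\,\mathrm{biochar}}\,
        \gamma(N)\, w_i(s)\, \varepsilon_i$$

with monoculture baselines $\mu_i$ (g per pot), a drought multiplier
$d \in (0,1]$, a biochar multiplier $b \ge 1$, a per-richness
complementarity boost $\gamma(N)$ (with $\gamma(1) = 1$), dominance weights
$w_i(s) \propto \exp(s z_i)$ ($z_i$ the standardized rank of $\mu_i$ within
the community, weights normalized to mean 1), and lognormal noise
$\varepsilon_i$ with mean 1 and coefficient of variation `cv`. Monocultures
use $N = 1$, $\gamma = 1$, $w = 1$, so their noiseless yield *is* the
baseline the partition estimates — the recovery loop is closed by
construction, not by coincidence.

Default parameters (all overridable) and why:

| parameter | default | rationale |
|---|---|---|
| `mu` | 4, 6, 8, 10, 12 g | per-pot dry biomass typical of small herbaceous species over one season, spread enough to make selection detectable |
| `drought_mult` | 0.7 | grassland drought studies commonly report ~30% biomass loss |
| `biochar_mult` | 1.3 | a productive amendment response of similar magnitude |
| `gamma` | 1, 1.15, 1.30 for N = 1, 2, 4 | modest overyielding growing with richness, keeping CE > 0 |
| `skew` | −0.5 | subordinate species overperform, giving SE < 0 without swamping CE |
| `cv` | 0.15 | multiplicative measurement/biological noise on positive, right-skewed biomass — hence lognormal, parameterized by CV for scale-freeness |
| `rsr_drought_mult` | 1.4 | root-to-shoot ratio rises under drought as allocation shifts belowground |

These magnitudes are illustrative study conditions, chosen once to match
the qualitative directions such experiments report (drought ↓ biomass,
biochar ↑, CE > 0, SE < 0); they are not estimates of any particular
dataset.

The dominance-weight construction is the minimal one-parameter mechanism
that produces selection effects of either sign while leaving the expected
complementarity interpretable: because the weights are normalized to mean
1, $\mathrm{CE} = (\gamma(N) - 1)\,\overline{M}$ at `cv = 0` regardless of
`skew`, and $\mathrm{SE} = \gamma \,\mathrm{cov}(w, M)$ takes the sign of
`skew`. Rank ties (equal $\mu_i$) use average ranks; an all-equal community
has zero rank variance and degrades cleanly to $w \equiv 1$.

Ground truth is computed by running the partition itself on the noiseless
yields (a self-oracle), avoiding a duplicated derivation that could be
wrong in the same way twice; an independently hand-derived closed form for
the two-species case is kept in the test suite as a cross-check.

Trait generation is deliberately thin: species-level constants with
lognormal noise, shoot/root split from the (drought-inflated) RSR, leaf
and root morphometrics consistent with the species' SLA and SRL baselines.
Traits do not feed back into yields. What the generator does *not* emulate
— and what passing recovery tests therefore cannot certify about real
data — includes density dependence and asymmetric competition, pot-level
(rather than species-level) error correlation, seedling mortality,
temporal dynamics, and any mechanistic soil–water–microbe coupling. The
generator validates the *arithmetic* of the pipeline, not the biology of
any particular greenhouse.

## Summaries and uncertainty

Group summaries use a seeded percentile bootstrap over pots within each
richness × treatment cell (default 2,000 replicates), preferred over
normal-approximation intervals at n = 5 pots per cell. The percentiles are
taken at *expanded* levels — $\alpha/2$ replaced by
$\Phi\!\left(t_{\alpha/2,\,n-1}\sqrt{n/(n-1)}\right)$ (Hesterberg's
small-sample correction) — because the plain percentile interval is known
to undercover for small samples (measured ~92.6% at n = 20 against a
nominal 95%); with expansion the measured coverage is ~94–95%. The raw
interval remains available via `expand = FALSE`.

Percent-change effect sizes (`percent_change()`) take explicit
reference/comparison pairs and make no assumption about which cells to
contrast. Mixed-model fitting itself (treatments as fixed effects, pot as
random intercept, Tukey post-hoc) is deliberately out of scope: that layer
is standard and well served by lme4/emmeans/multcomp; `export_model_table()`
emits the tidy long-format table those tools consume, with richness as a
factor and pot_id as the grouping variable.

## Numerical choices and problem sizes

* Additivity certificate tolerance: $10^{-9}$ relative — loose enough for
  accumulated rounding over $N \le 8$ species, tight enough that any
  conceptual error (e.g. a sample-covariance denominator) fails by many
  orders of magnitude. Observed residuals on randomized instances stay
  below $10^{-12}$ relative.
* Verification sizes used by the test suite and the acceptance script:
  10,000 randomized partitions for the additivity property, 1,000 for the
  closed-form-versus-brute-force comparison, 200 replicate mixtures for
  noisy recovery of an injected CE of 3 g, 100 simulated experiments for
  the CE > 0 / SE < 0 sign pattern, and 1,000 simulations at n = 20 for
  bootstrap coverage. These sizes put Monte-Carlo error well below the
  effects being checked while keeping a full run in tens of seconds.
* Seeding: every stochastic routine takes an explicit integer seed and
  restores the caller's RNG state (`withr`), so pipelines are reproducible
  end-to-end and tests cannot interact through hidden RNG state.

## Known limitations

* The partition requires a monoculture baseline for every mixture member
  under the relevant treatment; with fewer replicate communities than pool
  species at richness 1, some species have no monoculture and their
  mixtures are skipped (logged, never imputed).
* Relative yields divide by *estimated* baselines (monoculture means), so
  with few monoculture pots the estimated effects inherit that noise; the
  recovery report's Monte-Carlo standard errors quantify the consequence
  but the package makes no shrinkage correction.
* The tripartite extension of the partition (separating dominance from
  trait-dependent selection) and transgressive-overyielding statistics are
  not implemented.
* `percent_change()` is undefined at zero reference means and is reported
  per explicit pair only.
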