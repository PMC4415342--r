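---
title: "Scoring and ranking county health: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and ranking county health: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

healthrankr implements the composite-index methodology behind within-state
county health rankings, as popularized by the annual County Health Rankings:
a county-by-measure table goes in; within-state standardized scores, two
weighted composite indices with their six component scores, within-state
ranks, quartiles, unrankable flags, national benchmarks, and an
extremes comparison come out. This vignette explains the model, its tunable
constants, the numerical choices made where the method's published
description is silent, and what the synthetic data generator does and does
not emulate.

## The model

A county's health is summarized by two separate composite families: **health
outcomes** (the current state of health — mortality measured as premature
death, and morbidity) and **health factors** (modifiable determinants of
future health — health behaviors, clinical care, social and economic
factors, and the physical environment). Each family is a weighted sum of
measures; the default catalog is the 34-measure 2014 hierarchy, with
premature death (years of potential life lost before age 75 per 100,000)
carrying 50% of the outcomes family and the factor components carrying
30/20/40/10 percent of the factors family. The two families are never mixed
into one number: they answer different questions ("how healthy is this
county today?" vs "how healthy will it be?"), and a county can rank well on
one and poorly on the other.

Measures arrive on incommensurable scales (rates, percentages, survey
means), so each is standardized **within its state**:

$$Z = \frac{\text{county value} - \text{mean of counties in state}}
           {\text{SD of counties in state}}$$

Reverse-coded measures (where higher raw values mean better health, e.g.
high school graduation) are negated, so higher Z always means poorer
health. Weighted Z-scores are summed into the eight composites (two family
scores and six component scores, the components partitioning their family
score exactly), and counties are sorted within each state: the lowest
composite gets rank 1 (healthiest). Ranking within states rather than
nationally is a deliberate feature of the methodology — several source
measures are built from state-specific models and are not comparable across
state lines, and within-state comparisons are the ones that motivate local
action.

## Cell-level treatment: reliability, imputation, truncation

Three rules protect the ranks from small-area noise, applied in this order
inside `compute_zscores()`:

1. **Reliability (RSE > 20%)**: a value whose standard error exceeds 20% of
   its magnitude is flagged unreliable and excluded from scoring. A zero
   estimate with a positive standard error is unreliable by convention (the
   RSE diverges as the estimate goes to zero).
2. **State-mean imputation**: missing or unreliable cells receive Z = 0 —
   exactly equivalent to assigning the county its state's mean — with the
   state mean and SD computed from observed counties only. Imputed cells
   therefore contribute nothing to composites, and the imputation method is
   simple enough to explain to a non-technical audience, which is part of
   the methodology's design brief.
3. **Small-county truncation**: counties with 20,000 or fewer residents
   have Z clamped to ±3, damping outliers driven by small denominators.
   The band is symmetric, so direction-flipping and truncation commute.

A measure with fewer than two observed counties in a state (e.g.
particulate air pollution, unavailable statewide in Alaska and Hawaii) is
dropped for that state and the remaining weights of the same composite
family are renormalized proportionally to sum to 100. This keeps the
composite scale comparable across states rather than silently shrinking the
affected states' scores toward zero.

### Unrankable counties

A county cannot be credibly ranked when its mortality anchor is too weak:
(1) premature death missing; (2) premature death unreliable and no
morbidity measure available; (3) premature death *and* low birthweight
unreliable with no other morbidity measure available. Rule 3 is not
redundant with rule 2 only if "available" means *present*: rule 3 covers
the case where low birthweight is present but itself unreliable. We read
the rules that way; the first matching rule is recorded as the reason.
Unranked counties keep their rows (with flags) but occupy no rank position
and receive no quartile.

## Ranking conventions

The published description of the methodology is silent on several
conventions; the package fixes them as follows and exposes most as options
in `ranking_config()`:

- **SD flavor**: sample SD (n−1). A state's counties are treated as draws
  from a wider process; `sd_method = "population"` is available for
  matching other implementations. The choice never changes ranks — it is a
  uniform within-state rescaling — but it changes printed scores.
- **Ties**: competition ranking (ties share the minimal rank, the next rank
  is skipped), consistent with published ranks being integers. Output rows
  are ordered by state then FIPS so runs are byte-identical.
- **Quartiles**: quartile = ⌈4·rank / n_ranked⌉ clamped to 1–4, computed on
  outcomes and factors ranks over ranked counties only. Tied counties
  inherit their shared rank's quartile. Degenerate edge: a state with a
  single ranked county gets quartile 4 by the formula; we keep the formula
  rather than special-casing it.
- **National benchmark**: the best-10% boundary per measure across all
  counties with observed values (ranked or not), 10th percentile for
  higher-is-worse measures and 90th for reverse-coded ones, linear
  interpolation between order statistics (R's quantile type 7). Fewer than
  10 observed counties makes the benchmark unavailable rather than a
  guess.
- **Extremes comparison**: pools the 5 best- and 5 worst-ranked counties by
  outcomes rank from each state with at least 10 counties (smaller states
  are still ranked — the floor applies to this comparison only), and
  reports unweighted per-measure group means plus the least-healthy /
  healthiest ratio rounded to one decimal. Group means are unweighted
  across counties; mean population is reported as its own row. Boundary
  ties resolve by rank then FIPS, and in a state with fewer than 10 ranked
  counties the healthy set fills first so the groups stay disjoint.

## The synthetic generator

`simulate_counties()` exists so the whole pipeline can be validated without
licensed national data. Its generative model is deliberately minimal: one
latent "true health" factor per county, standard normal, lower = healthier.
Every measure is `baseline + sign · loading · latent + noise`, with the
sign chosen so unhealthy counties look unhealthy on every measure, and
baselines matching the magnitudes of the published 2014 all-county means
(`extremes_reference_2014()`). Defaults, chosen once as a realistic US-like
panel:

- **50 states**, four of them with fewer than ten counties (3, 5, 5, 8 —
  the CT/DE/HI/RI analogue), the rest spread 10–250 along a log-normal
  quantile grid, ~3,100 counties in all, so exactly 46 states enter the
  extremes comparison.
- **Populations** log-normal (meanlog 10.18, sdlog 1.1): median ≈ 26,000
  and ~40% of counties at or below the 20,000 truncation cutoff, so the
  truncation path is genuinely exercised.
- **Loadings** 15% of each measure's baseline per latent SD; **noise** half
  the loading ("moderate": per-measure latent–value correlation ≈ 0.89).
- **Standard errors** `60 · scale / sqrt(population)` for the eight
  survey/vital-statistics measures, making roughly the smallest 2% of
  counties unreliable on them.
- **Missingness** MCAR per measure, following the banded 2014 profile: 12
  measures complete, six at 0.5%, nine at 5%, six at 15%, and excessive
  drinking worst at 28%. Band membership follows data sources (survey
  measures most missing). Air pollution is additionally dropped wholesale
  in two small states to exercise weight renormalization.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: spatial autocorrelation between neighboring
counties, multi-factor correlation structure (one latent factor cannot
produce, say, behaviors and clinical care diverging), informative
missingness (real missingness concentrates in small rural counties; ours is
MCAR), heavy-tailed measure distributions, and real geographic marginals.

## Properties verified, and two subtleties

The test suite verifies: exact weight conservation of the default catalog;
within-state mean 0 / SD 1 of observed Z (tolerance 1e-9) before
truncation; truncation never increasing a magnitude and never touching
counties above 20,000; location-scale invariance of Z; equivalence of the
vectorized engine with naive per-cell and sort-based oracle
implementations over randomized small tables; permutation invariance of all
ranks; byte-identical outputs across repeated runs; exact recovery of the
latent within-state ordering under zero noise and missingness; and
Spearman ρ > 0.9 between latent health and outcomes rank under the default
moderate noise with the full missingness and reliability machinery active.

Two subtleties deserve honest statement. First, rank recovery is measured
over counties whose premature-death value survived the missingness and
reliability masking: a county whose 50%-weight anchor was masked is imputed
to the state mean and carries no recoverable outcome signal, so including
it would measure the simulated data destruction rather than the method.
Second, rank monotonicity — worsening one value never improves the
county's rank — holds for cells whose reliability status is stable, and is
asserted as such (1,000 random perturbations of reliable cells). It is
*not* unconditionally true of the method: worsening an unreliable value
can push its RSE below the 20% cutoff, replacing the state-mean imputation
with an observed below-average value and legitimately improving the rank.
That is a real, if exotic, property of the RSE rule, not a defect of this
implementation.

## Problem sizes

Tests and the acceptance script run on synthetic panels of: 46–50 states
(~2,700–3,200 counties, the scale of the real national table) for the
normalization, truncation, and group-size checks; 6 states of 80–120
counties for rank recovery (large enough that per-state Spearman estimates
reflect the method rather than small-sample scatter); 100 randomized
two-state tables of 2–6 counties per state for oracle equivalence; and
1,000 single-value perturbations of a 5-state panel for monotonicity.

## A worked example

```{r, eval = FALSE}
library(healthrankr)

sim <- simulate_counties(simulation_config(n_states = 50, seed = 1))
res <- run_rankings(sim$table)
#> counties: 3203 ranked, 19 unranked (0.6%)
#> cells: 6142 imputed, 88 truncated, 725 unreliable

head(res$rankings[c("fips", "state", "outcomes", "rank_outcomes",
                    "quartile_outcomes")])
res$extremes[res$extremes$measure_id %in%
               c("n_counties", "premature_death"), ]
```

The extremes table on real 2014 data shows the methodology's headline
finding: the five least healthy counties of each state have roughly twice
the premature death rate of the five healthiest (published means 10,862 vs
5,113 years of potential life lost per 100,000; `extremes_ratio()` gives
2.1).
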