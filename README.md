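# healthrankr

Composite health scoring and within-state ranking of counties, in the style
of the annual *County Health Rankings*: a reusable, offline-testable
implementation of the full methodology for epidemiologists, state health
departments, and anyone adapting the model to their own measures and
weights.

From a county-by-measure table (FIPS code, state, population, one column
per measure, optional standard-error columns) the package computes:

- **within-state Z-scores** per measure,
  `Z = (county value − state mean) / (state SD)`, with state-mean
  imputation of missing cells, a 20% relative-standard-error reliability
  filter, reverse-coding of measures where higher is better, and truncation
  of |Z| > 3 for counties with ≤ 20,000 residents;
- **eight weighted composite scores** per county — health outcomes
  (mortality + morbidity) and health factors (health behaviors, clinical
  care, social & economic, physical environment) — using the 2014
  34-measure catalog by default (premature death alone carries 50% of the
  outcomes family), with per-state weight renormalization when a measure is
  unavailable statewide;
- **within-state competition ranks** (rank 1 = healthiest) for all eight
  composites, **quartiles** of the outcomes and factors ranks, and
  **unrankable flags** for counties whose premature-death data are missing
  or unreliable without sufficient morbidity data;
- **national best-10% benchmarks** per measure and a **least-healthy vs
  healthiest extremes table** pooling the 5 worst- and 5 best-ranked
  counties per state (states with ≥ 10 counties).

A synthetic multi-state generator (`simulate_counties()`) with a known
latent "true health" factor, US-like populations and the 2014 missingness
profile makes every stage testable without licensed national data.

## Worked example

```r
library(healthrankr)

sim <- simulate_counties(simulation_config(n_states = 50, seed = 1))
res <- run_rankings(sim$table)
#> counties: 3203 ranked, 19 unranked (0.6%)
#> cells: 6142 imputed, 88 truncated, 725 unreliable

head(res$rankings[c("fips", "state", "outcomes", "factors",
                    "rank_outcomes", "quartile_outcomes")])
#>   fips  state outcomes factors rank_outcomes quartile_outcomes
#> 1 01001 S01    -0.699   -1.00              1                 2
#> 2 01002 S01    -0.298    0.351             2                 3
#> 3 01003 S01     0.997    0.654             3                 4
#> 4 02001 S02    -0.567   -0.205             1                 1
#> ...
```

The 19 unranked counties are small places whose premature-death estimate
was missing or unreliable; the 88 truncations are Z-scores clamped to ±3 in
counties of ≤ 20,000 residents. The extremes table reproduces the
methodology's headline contrast — least-healthy counties carry roughly
twice the premature death of the healthiest:

```r
res$extremes[res$extremes$measure_id %in%
               c("n_counties", "premature_death"), ]
#>   measure_id        all  least_healthy healthy  others  ratio_lh_h
#> 1 n_counties      3182      230          230     2722       NA
#> 2 premature_death 7718.3    9887.5       5600.8  7713.9     1.8
```

On the published 2014 data (shipped as `extremes_reference_2014()`), the
same ratio computation gives 2.1: least-healthy counties averaged 10,862
years of potential life lost per 100,000 against 5,113 for the healthiest.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/healthrankr.R simulate --states 50 --seed 1 --output counties.csv
Rscript inst/cli/healthrankr.R rank --input counties.csv --output-dir out/
Rscript inst/cli/healthrankr.R validate --input counties.csv
Rscript inst/cli/healthrankr.R export-catalog --output catalog.json
```

Custom catalogs (different measures, weights, directions) are first-class:
export the default, edit it, and pass `--catalog` / `catalog =` anywhere.

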