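# batwind

Full-annual-cycle habitat modelling and wind-energy siting conflict analysis
for a migratory bat (modelled on the Mexican free-tailed bat, *Tadarida
brasiliensis mexicana*). Wind-turbine collision risk for migratory bats is
seasonal — the species' distribution shifts across its annual cycle — so the
package models habitat suitability **per season** from presence-only
specimen records, scores the landscape for turbine siting with a weighted
multi-criteria overlay, and intersects the two into conflict products for
siting and curtailment decisions.

The workflow, end to end:

1. **Occurrence cleaning** — keep 1970–2020 preserved specimens with
   complete dates, split into meteorological seasons, drop exact coordinate
   duplicates, and spatially rarefy to a 10-km minimum-distance window.
2. **Seasonal niche models** — presence-background maximum-entropy models
   over background cells $z_b$,
   $q_\lambda(z) = e^{\lambda\cdot f(z)}/Z_\lambda$, with linear, quadratic
   and product (LQP) features plus land-cover indicators, fitted by
   maximizing the L1-regularized training gain
   $J(\lambda) = \tfrac1m\sum_i \lambda\cdot f(x_i) - \log(Z_\lambda/B)
   - \sum_j \beta_j|\lambda_j|$
   with a coordinate-descent solver verified against dense-search oracles
   (KKT residual ≤ 1e-6). The regularization multiplier is selected from
   0.5–5 (step 0.5) by AICc; evaluation is 5-fold cross-validated
   Mann–Whitney AUC; logistic output gives a 0–1 suitability index.
3. **Habitat classes** — the 10% and 50% training-omission thresholds slice
   each seasonal suitability map into unsuitable / low-to-moderate / high
   habitat.
4. **Siting suitability** — six criteria (wind power class, slope, land
   cover, population density, distance to roads and to transmission lines)
   reclassified to 0–4 and summed with weights 3/2/2/2/2/1 into a 0–48
   score, banded at 16/32 into low / moderate / high siting classes, with
   military, protected and 1-km airport-buffer exclusions as NoData.
5. **Conflict products** — turbines (capacity > 65 kW, rotor > 30 m)
   tabulated by seasonal habitat class (unlikely / moderate / high
   potential impact), high-siting cells classed minimum / low / high
   potential conflict by the habitat beneath them, and 100-km roost-buffer
   overlap summaries.

Real inputs (occurrence downloads, climate and land-cover rasters, turbine
databases) are accepted as files — ESRI ASCII grids, CSV, GeoJSON — but the
package also ships a seeded synthetic-landscape generator with known truth
(`generate_env_stack()`, `compute_truth_suitability()`,
`sample_presences()`, `generate_siting_criteria()`, `generate_turbines()`),
so the whole pipeline runs with no external data and parameter recovery is
tested, not assumed.

## Worked example

The numbered drivers under `analysis/` run the whole study on a seeded
100 × 100 km synthetic scene (1-km habitat grid, 300-m siting grid) and
write their tables and rasters under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_prep_occurrences.R
Rscript analysis/03_fit_models.R
Rscript analysis/04_habitat_maps.R
Rscript analysis/05_siting_suitability.R
Rscript analysis/06_conflict_overlap.R
```

Stage 2 prints the record funnel — 800 raw records, minus incomplete dates
and non-specimen records, then per-season dedup and 10-km thinning:

```
 season filtered deduped thinned
 spring      195     193      56
 summer      185     184      56
   fall      186     183      51
 winter      187     184      53
```

Stage 3 fits the four seasonal models (regularization multiplier chosen by
AICc, then 5-fold cross-validated test AUC, mean ± sd):

```
spring: m=56, rm=1.5 (AICc), 3 nonzero features, test AUC 0.630 +/- 0.065
summer: m=56, rm=1.0 (AICc), 4 nonzero features, test AUC 0.596 +/- 0.027
fall:   m=51, rm=1.5 (AICc), 2 nonzero features, test AUC 0.638 +/- 0.098
winter: m=53, rm=2.0 (AICc), 1 nonzero features, test AUC 0.580 +/- 0.056
```

AUCs near 0.6 are the expected regime here: the synthetic truth uses
moderate effect sizes, and ~55 presences against a shared background leave
limited signal — comparable to real seasonal specimen sets. Stage 4 turns
training-omission thresholds into habitat classes:

```
spring: thresholds 0.4286 / 0.5101 -> 28.7% unsuitable, 39.1% low-moderate, 32.2% high
```

and stage 6 reports where existing turbines fall (counts and percentages
per impact class, summing to the 500 generated turbines per season) and the
pooled roost-buffer overlap:

```
high-impact turbine share peaks in winter (37.4%)
pooled 100-km roost buffers hold 500 turbines and 768 km2 of high-siting area
```

Equivalently, `run_pipeline(pipeline_config(seed = 7), "out_dir")` executes
all stages in one call and writes a provenance manifest (config hash,
per-stage seeds, selected multipliers, thresholds) sufficient to reproduce
every output byte-identically.

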