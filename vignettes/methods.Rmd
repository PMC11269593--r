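---
title: "Methods: seasonal habitat models and wind-siting conflict analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal habitat models and wind-siting conflict analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Migratory bats such as the Mexican free-tailed bat (*Tadarida brasiliensis
mexicana*) collide with wind turbines at high rates, and the risk is
seasonal: the species' distribution shifts across its annual cycle, so a
single pooled habitat map understates exposure during migration. `batwind`
implements a full-annual-cycle workflow that (i) models seasonal habitat
suitability from presence-only specimen records, (ii) scores the landscape
for wind-turbine siting with a weighted multi-criteria overlay, and (iii)
intersects the two — plus existing turbine locations and roost buffers —
into conflict products. Because the real inputs are large external
geodatabases, the package ships a seeded synthetic-landscape generator with
known truth, so every stage is testable end to end and parameter recovery
can be verified rather than assumed.

# The seasonal niche model

## Model form

Habitat suitability is estimated with a presence-background maximum-entropy
(Maxent-type) model. Over the background cells $z_1,\dots,z_B$ the model is
the Gibbs density

$$q_\lambda(z) = \frac{e^{\lambda \cdot f(z)}}{Z_\lambda}, \qquad
Z_\lambda = \sum_b e^{\lambda \cdot f(z_b)},$$

with feature vector $f$ built from the environmental variables: each
continuous variable is min–max scaled to $[0,1]$ on its training range and
expanded into linear, quadratic and pairwise-product (LQP) features;
land cover enters as one indicator per observed class. Evaluation values
outside the training range are clamped to the bounds, so extrapolation is
flat rather than explosive. The coefficients maximize the regularized
training gain

$$J(\lambda) = \frac1m \sum_{i} \lambda \cdot f(x_i)
  - \log \frac{Z_\lambda}{B} - \sum_j \beta_j |\lambda_j|,$$

an L1-penalized concave objective; the penalty
$\beta_j = \mathrm{rm} \cdot c_{\text{class}(j)} \cdot
\max(\mathrm{sd}_j, \varepsilon)/\sqrt{m}$ scales with the feature's
standard deviation over the $m$ presences, a single base constant per
feature class (all 1 by default), and the tunable regularization multiplier
rm. This preserves the qualitative regularization mechanism of the
reference Maxent implementation without reproducing its unpublished
per-feature interpolation tables; the constants are configurable through
`reg_schema()`.

The solver is cyclic coordinate descent with a per-coordinate proximal
Newton step and objective-based backtracking. Convergence is declared on
the KKT residual of the L1 problem at tolerance $10^{-6}$: for
$\lambda_j = 0$, $|g_j| \le \beta_j + \text{tol}$, otherwise
$|g_j - \mathrm{sign}(\lambda_j)\beta_j| \le \text{tol}$, where $g_j$ is
the presence mean of feature $j$ minus its expectation under $q_\lambda$.
The tests check this contract directly and also compare fitted coefficients
against dense grid-search and golden-section maximization of $J$ on one- and
two-feature problems. Non-convergence is returned explicitly
(`converged = FALSE`, with a warning), never silently.

## Output scale

The raw density is rescaled to the familiar 0–1 logistic suitability index
at an assumed prevalence $\tau = 0.5$:
$\text{logistic}(x) = r e^H / (1 + r e^H)$ with $r = q_\lambda(x)$ and $H$
the entropy of the fitted background distribution. With $\lambda = 0$ the
output is exactly 0.5 everywhere. The omission-rate habitat thresholds are
applied to this logistic output (the raw scale would give identical class
maps for monotone thresholds derived from the same training values, but the
logistic scale is the one users see, so thresholds are defined there and
recorded in the artifacts).

## Model selection and evaluation

The regularization multiplier is chosen from the grid 0.5, 1.0, …, 5.0 by
the small-sample AIC: raw densities are renormalized over the evaluation
extent (the training background by default; the exact normalization extent
of the reference tooling is not documented, so this is a config switch),
$k$ counts nonzero coefficients, and
$\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(m-k-1)$, undefined when $k = 0$ or
$k \ge m-1$; undefined candidates are excluded and ties go to the smaller
multiplier. The grid starts at 0.5 rather than 0 because the unpenalized
fit can diverge under complete separation.

Performance is summarized by the rank-based (Mann–Whitney) AUC of presence
versus background scores, with ties counted one half, under a seeded
5-fold random cross-validation of the presences against the shared
background. The replicate scheme behind published mean ± sd testing AUCs is
rarely stated; random k-fold is the package's documented choice.

Variable importance is permutation importance: each variable is permuted
across evaluation rows (jointly over all features derived from it) and the
mean drop in training AUC, floored at zero, is normalized to percentages
summing to 100. The reference tool's path-dependent "percent contribution"
heuristic is not reproducible from its published description; permutation
importance measures the same quantity model-agnostically. A collinearity
screen (pairwise Pearson r at the background sample, flag threshold 0.7)
is reported but never drops variables automatically — strongly correlated
pairs can legitimately be retained, as the source analyses do.

# Occurrence cleaning

Records are kept if they are preserved specimens (basis matched
case-insensitively, ignoring separators) from 1970–2020 with complete
dates; they are split into meteorological seasons (Mar–May, Jun–Aug,
Sep–Nov, Dec–Feb), deduplicated on exact coordinates within season, and
spatially rarefied so no two retained records lie within 10 km. Thinning is
per season: the seasonal record counts any pooled-then-split variant would
produce are inconsistent with published per-season counts, so per-season is
the recorded interpretation. The thinning algorithm greedily removes the
record with the most neighbours inside the window (seeded uniform
tie-breaks); the contract is the postcondition — all pairwise distances at
least the window — not the heuristic, and it is verified against an
all-pairs oracle and for idempotence. Distances are haversine for
geographic coordinates and Euclidean (metres) for projected ones; the
toolbox used in the source workflow does not state its metric.

# Habitat classes from omission rates

The threshold at training-omission rate $r$ is the
$(\lfloor r m \rfloor + 1)$-th smallest training-presence suitability, so
at most $\lfloor r m \rfloor$ training presences fall strictly below it,
and with distinct values exactly that many — deriving the 10% threshold
from 200 distinct training values and reclassifying them reproduces a 10%
training omission exactly. Cells below the 10% threshold are unsuitable,
cells from there up to (excluding) the 50% threshold are low-to-moderate,
and cells at or above it are high-suitability habitat. The published rule
gives rates, not inequalities; the half-open convention (`< t_low`,
`>= t_high`) makes the classes exhaustive and monotone in suitability.

# Siting suitability

Six criteria — wind power class, slope, land cover, population density,
distance to roads, distance to transmission lines — are each reclassified
to ordinal 0–4 scores (4 most suitable) and combined as a weighted sum with
weights 3, 2, 2, 2, 2, 1 respectively, giving a 0–48 composite banded into
low (0–16), moderate (17–32) and high (33–48) siting suitability. The
weights, score range and bands are fixed by the published scheme; the
breakpoint tables inside each criterion are shipped as documented,
overridable defaults in the style of the GIS siting literature (the source
supplement's exact tables are not published in the available text, so they
are never asserted as ground truth). Reclassification bins are half-open
`[from, to)` — a value on an interior breakpoint takes the upper bin — with
explicit errors for gaps in coverage.

Military land, protected areas (levels 1–2) and 1-km airport buffers are
excluded. Exclusions become NoData rather than score 0, so excluded area
can never be read as "low suitability"; the source describes such areas as
unsuitable for generation, and NoData is the interpretation that keeps them
out of every denominator. The distance criteria are exact point-to-segment
Euclidean distances from cell centers; the analysis grid is 300 m by
default (the published common resampling resolution), while habitat is
modelled at 1 km.

# Overlap products

Each turbine (filtered to capacity strictly above 65 kW and rotor strictly
above 30 m, when the attributes are present) is assigned the habitat class
of its containing cell per season — unlikely / moderate / high potential
impact, with off-map turbines reported explicitly — using the total
supplied turbine set as the percentage denominator. Conflict maps mark
high-siting cells as minimum / low / high potential conflict according to
the seasonal habitat class beneath them (habitat regridded to the siting
grid by nearest neighbour; the published workflow is silent on grid
reconciliation). Roost-buffer summaries count turbines and
high-siting area within 100 km of each roost and of the union of all
roosts; membership is computed from point distances rather than discretized
buffer polygons, which is exact for point roosts.

Cell ownership follows one convention everywhere: half-open cells anchored
at the top-left, floor indexing, so a point on a vertical edge belongs to
the right-hand cell. CRS identifiers are opaque metadata — the package
never reprojects; all inputs to one analysis must share a declared CRS, and
projection (e.g. to a Lambert conformal conic) is the caller's
responsibility upstream.

# The synthetic landscape

The generator emulates the statistical structure the analysis assumes, not
any real geography: continuous fields are white noise smoothed with a
uniform disk kernel (radius `autocorr_len` cells — a cheap autocorrelation
device, not a Gaussian-process claim) and affinely rescaled to realistic
moments (temperature 15 ± 8 °C, solar radiation 15000 ± 3000 kJ m⁻² day⁻¹,
vapour pressure 1.2 ± 0.4 kPa, wind speed 4 ± 1.5 m s⁻¹, seasonal
precipitation 60 ± 30 mm). Seasonal fields share a common component (weight
0.5) so seasons differ but correlate, as real climate layers do; land cover
is quantile-sliced from one smoothed field and held constant across seasons,
as in real land-cover products. Truth suitability is a logistic transform of
a linear predictor over standardized variables with known coefficients
(default: temperature +1.2, vapour pressure +1.0, wind speed −0.8 —
moderate effects on the standardized scale chosen to mimic the weakly
discriminable regime of the real system, where testing AUCs sit in the
0.6–0.8 range). Presences are sampled with replacement proportional to
truth, at cell centers, with duplicate retention and a 5% observation-type
contamination plus 2% missing months injected deliberately so the cleaning
funnel has real work to do. Turbines are placed with probability
$\propto e^{\text{bias} \cdot \text{wind class}}$ (bias 1), emulating
preferential siting.

What passing tests on this generator do **not** show: robustness to
geocoding error, sampling bias beyond what thinning removes, non-stationary
species–environment relationships, or land-cover change over the record
period — none of which the synthetic scenes contain. Parameter-recovery
results (Spearman ρ ≥ 0.9 between predicted and truth suitability on a
100 × 100 scene with m = 500, B = 5000) demonstrate the estimator works
when its assumptions hold, not that real-data models attain that fidelity.

# Numerical choices and problem sizes

Solver: KKT tolerance 1e-6, at most 2000 coordinate sweeps, penalty sd
floor 1e-4. Mode-block regridding breaks ties toward the smallest class;
the airport buffer is inclusive at exactly 1 km. The default end-to-end
configuration uses a 100 × 100-cell 1-km habitat grid (334 × 334 at 300 m
for siting), 200 raw presences per season (≈ 50–60 after cleaning, matching
the scale of real seasonal specimen sets), a background of 2000, the full
ten-candidate rm grid and 5-fold cross-validation; one full run takes a few
seconds, and the whole test suite under a minute, so the study conditions
are exercised directly rather than in miniature. Background size 10,000 is
the default for standalone `sample_background()` calls, matching common
practice; the pipeline default of 2000 reflects its 10,000-cell scene
(background cannot exceed the valid-cell count, and a 20% background sample
is already near-exhaustive for model purposes).

# Known limitations

Single-ring polygons only (no holes); no reprojection; no hinge/threshold
features or cloglog output; the AICc extent is the training background
rather than the full study extent unless overridden; permutation importance
is not numerically comparable to the reference tool's percent contribution
even though both rank variables similarly in clean scenes.
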