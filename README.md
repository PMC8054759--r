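# migrascape

Seasonal species-distribution ensembles and migratory-corridor inference
from presence-only occurrence records.

## The problem

For small-bodied migrants such as tree bats, individual tracking at
continental scale is mostly infeasible, yet delineating their migratory
corridors matters — for these species most wind-turbine mortality coincides
with autumn migration. What *is* available at scale are presence-only
occurrence archives and gridded monthly environmental layers. `migrascape`
implements the inference chain that turns those into corridor hypotheses:

1. **Occurrence preparation** — coordinate/record-type/recency filtering,
   spatial thinning to one record per grid cell (sampling-bias control),
   seasonal labelling (Dec–Feb winter, Mar–May spring, Jun–Jul summer,
   Aug–Oct fall), pseudo-absence sampling and k-fold assignment.
2. **Predictor screening** — pairwise Pearson correlations between
   environmental layers; one member of each pair with |r| > 0.8 is dropped
   by a biological-preference order.
3. **Per-month suitability models** — four presence-background algorithms:
   a BIOCLIM climate envelope (score `min_v 2·min(p_v, 1−p_v)` over
   predictor percentile ranks), a logistic GLM with quadratic terms, a
   MaxEnt-style L1-penalized logistic model on
   linear + quadratic + product features, and a 500-tree random forest.
   Models are evaluated by cross-validated AUC and the True Skill Statistic
   (TSS = sensitivity + specificity − 1, maximized over thresholds) and
   combined into a **TSS-weighted ensemble**.
4. **Corridor inference** — monthly ensembles are averaged into spring /
   fall conductance surfaces; corridors are delineated three ways on a
   shared 8-connected raster graph (edge cost = length × mean endpoint
   resistance): least-cost-path density between all winter × summer
   endpoint pairs (Dijkstra), circuit-theory current maps (sparse Kirchhoff
   solve; winter/summer points as sources/grounds by migration direction),
   and the 95th-percentile suitability mask. Cells flagged by all three
   form the consensus corridor.
5. **Statistics** — Moran's I and Geary's C of the path-density surface
   (binary queen weights, permutation p-values) test whether proposed
   pathways cluster positively; a one-sided paired t-test asks whether
   least-cost ground distances exceed great-circle distances.

Because real occurrence/climate downloads are out of scope, the package
ships a first-class **synthetic-data generator**: monthly predictor rasters
(gradient + seasonal sinusoid + smoothed Gaussian field), a temperature
niche whose suitable band shifts ~south in winter / north in summer, a
planted low-elevation corridor with a known suitability boost, and biased
presence-only sampling. Every pipeline stage can therefore be validated
against ground truth.

## Worked example

```r
library(migrascape)

cfg <- pipeline_config(seed = 1, out_dir = "run1")
res <- run_pipeline(cfg)
print(res)
#> pipeline_result
#>   occurrences: 3600 raw -> 865 prepped
#>   predictors retained: precip, tavg, wind, human, elev, ndvi, forest
#>   ensemble test AUC: 0.793 (mean over months), TSS: 0.538
#>  season  morans_i morans_p  gearys_c gearys_p mean_increase_km t_p
#>  spring 0.3426233     0.01 0.6784102     0.01         136.4034   0
#>    fall 0.2940346     0.01 0.7279468     0.01         170.1831   0
```

Reading the output: 3,600 sampled presence records thin to 865 after
filtering and 1°-cell thinning; the correlation screen drops two of the
nine predictors (vapor pressure at r = 0.97 and solar radiation at
r = 0.91, both collinear with average temperature);
the TSS-weighted ensemble's cross-validated AUC averages 0.79 across
months (above the median individual model, 0.70). Both seasonal
least-cost-path density surfaces cluster positively (Moran's I ≈ 0.3 at
the permutation floor p = 0.01; Geary's C < 1 agrees), and inferred paths
run on average 136 km (spring) / 170 km (fall) longer than the straight
line between their endpoints (paired one-sided p ≈ 0) — the corridors
follow landscape structure rather than beelines. On this run the planted
corridor's cells are ~14× (spring) / ~12× (fall) over-represented among
consensus-3 cells relative to their 5% background share.

Artifacts (ASCII-grid rasters, CSV tables, a hashed run manifest) land in
`run1/`; two runs with the same config and seed are byte-identical.

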