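---
title: "Inferring seasonal distributions and migratory corridors from presence-only data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring seasonal distributions and migratory corridors from presence-only data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrascape)
```

## The model

`migrascape` infers where a seasonally migrating species is and how it
moves between its seasonal ranges, using only presence records and monthly
environmental rasters. The chain has three statistical layers.

**Suitability.** For each month, presence points plus uniformly drawn
pseudo-absence ("background") points are scored by four
presence-background models:

* *BIOCLIM envelope.* For predictor $v$ with training-presence percentile
  rank $p_v(x)$ of a candidate value $x$, the tail score is
  $s_v = 2\min(p_v, 1 - p_v)$ and the overall score is $\min_v s_v$,
  clipped to $[0,1]$. Scores depend only on ranks, so the model is
  invariant to monotone transforms of any predictor. Ranks use the weak
  inequality ($\le$); a constant predictor scores 1 at its constant and 0
  elsewhere.
* *Logistic GLM* on standardized predictors with quadratic terms, so
  unimodal (niche-optimum) responses are representable.
* *MaxEnt-style model*, fit in its penalized-logistic equivalence: an
  L1-regularized logistic regression on linear, quadratic and pairwise
  product features of the standardized predictors, with penalty
  $\lambda = w\sqrt{\log(p)/n}$ ($w$ = `reg_weight`, default 1 — the
  $1/\sqrt{n}$ shrinkage mirrors MaxEnt's default regularization).
  Sequential feature induction and hinge/threshold features are
  deliberately out of scope.
* *Random forest* classifier, 500 trees, $\lfloor\sqrt{p}\rfloor$
  variables per split (the cited package defaults); the score is the
  presence-vote fraction.

**Evaluation and ensembling.** Each algorithm is evaluated by k-fold
cross-validation (default $k = 5$, i.e. 80% training / 20% testing per
fold) on rank-based AUC and the True Skill Statistic,
$\mathrm{TSS} = \text{sensitivity} + \text{specificity} - 1$, maximized
over candidate thresholds (midpoints of sorted unique scores; ties broken
toward the lower threshold). Monthly suitability rasters are combined as a
weighted mean with weights $\max(\mathrm{TSS}, 0)$ normalized to sum to
one — a worse-than-chance model contributes nothing rather than
subtracting signal; whether to normalize at all is immaterial after the
division. Ensemble rasters are winsorized at the 99th percentile (the
configurable reading of "outlier cells removed") and min–max rescaled to
$[0,1]$. Variable importance uses one unified permutation procedure
(baseline AUC minus mean AUC after permuting a column) in place of
per-package importance functions, preserving the rank semantics.

**Connectivity.** Spring (Mar–May) and fall (Aug–Oct) conductance surfaces
are the cell-wise means of those months' ensembles, floored at $10^{-6}$.
One 8-connected graph serves both corridor solvers: for neighbouring cells
$i, j$ at distance $\ell$ (1 rook, $\sqrt2$ diagonal, in cell units), edge
cost is $\ell\,(r_i + r_j)/2$ with $r = 1/c$, and edge conductance is
$(c_i + c_j)/2\,/\,\ell$. The symmetric mean-resistance /
mean-conductance discretization keeps the least-cost and circuit layers
consistent on a single graph. Corridors are then delineated by

1. *least-cost-path density*: one Dijkstra path per (winter point, summer
   point) pair; density = number of paths through a cell;
2. *circuit theory*: grounds at 0 V, total current 1 A split equally over
   sources (all-to-one mode, mirroring a single source-set/ground-set per
   season and direction; winter→summer in spring, summer→winter in fall);
   node current = half the sum of absolute incident edge currents, from a
   sparse solve of the reduced Kirchhoff system;
3. the *95th-percentile mask* of the seasonal suitability surface.

Density and current are binarized at their own 95th percentiles (one
consistent rule with the suitability mask; the threshold is
configurable), and the consensus counts agreeing methods per cell;
consensus-3 cells are the corridor candidates.

**Statistics.** Moran's I and Geary's C of the path-density raster use
binary queen contiguity, not row-standardized — binary weights keep the
checkerboard closed forms ($I = -1$, $C = 2(N-1)/N$) exact and are the
common raster default. The density raster enters whole, zeros included:
the statistics measure corridor concentration against background, which is
the stated purpose. Significance comes from random-labelling permutation
(default 99 permutations; $p = (1 + \#\{\text{at least as clustered}\}) /
(n_{perm} + 1)$, so the attainable floor is $p = 0.01$) rather than a
normal approximation — distribution-free, and the $+1$ estimator makes the
p-values valid (sub-uniform) by construction. Tests are one-sided
throughout, because the scientific claims are directional (positive
clustering; paths longer than straight lines). Distances are great-circle
(haversine, $R = 6371$ km) between cell centers.

## The synthetic landscape

The generator stands in for gridded climate archives and public occurrence
databases, with known ground truth.

Each of nine predictor layers (precipitation, solar radiation, average
temperature, vapor pressure, wind speed, human influence, elevation, NDVI,
forest cover) is *base + gradient·row + amplitude·cos(2π(month − 7)/12) +
noise*, where the noise is white Gaussian noise blurred with a one-cell
Gaussian kernel — spatially autocorrelated, as real predictors are; pure
white noise would make the estimation problem unrealistically atypical.
The noise field is drawn once per layer and held fixed across months, so
static layers (elevation, human influence) are genuinely static and all
monthly variation is seasonal. True suitability is a Gaussian kernel
around a monthly temperature optimum,
$\exp(-(T - \mu_m)^2 / 2\sigma^2)$, plus an additive boost inside a
buffered corridor polyline, capped at 1.

The reference study conditions (`pipeline_config()` defaults) are a
60 × 60 grid of 0.25° cells; temperature gradient 0.5 °C per row with a
±10 °C seasonal cycle, so a fixed 15 °C optimum makes the suitable band
sit ~40 rows apart between January and July — distinct winter and summer
ranges; 300 presences per month with a logistic eastward sampling bias
(the institutional bias of public archives); 1,000 pseudo-absences per
month; corridor boost 0.3 on a 3-cell-wide polyline.

Two generator choices deserve their rationale:

* *Niche breadth is 2 °C.* With a broad niche the three-month seasonal
  averaging smears suitability into a wide swath that connects the ranges
  everywhere, and the planted "corridor" is then not actually the
  preferred route even under the true suitability — the ground-truth label
  would be wrong. A 2 °C breadth (plausible for a thermally constrained
  migrant) keeps the seasonal ranges distinct so the corridor is genuinely
  load-bearing for between-range movement.
* *The corridor is a landscape feature, placed centrally.* The polyline
  also imprints the predictor stack (an elevation depression of 250 m and
  an NDVI boost — a river-valley analogue), because a corridor visible
  only in occurrence density and in no predictor would be unlearnable by
  any environmental model. It runs through the domain center, placed
  independently of the bias edge; sampling bias already drags endpoints
  eastward, and corridor placement should not be confounded with it.

What the generator does *not* emulate: coastlines and masked water, range
boundaries not driven by temperature, spatially varying observation effort
beyond one smooth gradient, taxonomic misidentification, and any
predictor interactions in the true niche. Passing recovery tests therefore
show that the pipeline recovers the truth *of this data-generating
process*; they do not certify performance on real archives, where bias
structure and niche complexity are harsher.

## Numerical choices and degenerate inputs

* Percentiles everywhere use linear interpolation between order statistics
  (R's type 7) — one stated dialect.
* Correlation screening compares $|r|$ with a strict threshold
  (default 0.8); anticorrelated redundancy is treated like correlated
  redundancy. Pairs are processed greedily in descending $|r|$, and the
  preference order (average temperature first) is configuration, since
  "biological relevance" is not computable.
* Thinning keeps the first record in input order — deterministic and
  idempotent; the thinning grid is anchored at integer degrees
  (`floor(coord / cell)`).
* November belongs to no season and is labelled `unassigned`; seasonal
  month sets are winter Dec–Feb, spring Mar–May, summer Jun–Jul, fall
  Aug–Oct.
* The k-fold split is read as the conventional 80% training / 20% testing
  per fold (the transposed wording in circulation would train on 20%,
  contradicting standard k-fold usage).
* Zero-variance layers make correlations undefined (reported as NA with a
  note); constant rasters are rejected by normalization, percentile masks
  and the autocorrelation statistics; all-zero sampling weights, empty
  designs, unreachable path endpoints and source–ground disconnection
  raise dedicated errors. Perfect separation in the GLM proceeds under
  suppressed convergence warnings (the penalized MaxEnt fit handles it by
  regularization). When a winter and a summer point share a grid cell, the
  cell stays a ground and is dropped from the sources — a cell cannot
  inject and sink at once.
* Least-cost ties are broken deterministically by the graph library's
  Dijkstra implementation; with real-valued conductances exact cost ties
  are practically confined to uniform grids, and all outputs are
  deterministic given the configuration seed. A single master seed derives
  every stage seed by fixed offsets.
* Monthly sample-size guards: warn below 25 occurrences, refuse below 13
  unless overridden (the published adequacy thresholds for wide-ranging
  species).

## Problem sizes

The shipped validation suite runs the reference study (60 × 60 cells,
3,600 presences before preparation, 12 monthly fits of 4 algorithms under
5-fold cross-validation, ~8,000 endpoint pairs per season) once, plus a
24 × 24 determinism replicate; the exact-oracle checks (path enumeration,
circuit closed forms, statistic closed forms) use grids up to 7 × 7 where
brute force is exact and instant. These sizes were chosen so the full
suite exercises every stage end to end in a few minutes on one core.

## Known limitations

* Rasters are unprojected lon/lat grids; cell-unit edge lengths ignore the
  poleward convergence of meridians (distances in the statistics layer use
  the haversine and are unaffected). At mid-latitude continental scale the
  graph-length distortion is modest; a projected-grid mode would remove
  it.
* All-to-one circuit mode concentrates current near the endpoint sets;
  current hotspots adjacent to sources or grounds should be read with
  care (pairwise mode is the standard alternative and is not implemented).
* The MaxEnt equivalence omits hinge/threshold features, so sharply
  truncated responses are approximated by quadratics.
* File formats: rasters are ESRI ASCII grids (plain text, single band);
  tables CSV; the manifest JSON. No GeoTIFF/GeoJSON writers.
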