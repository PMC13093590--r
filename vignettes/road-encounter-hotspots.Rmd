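---
title: "Predicting road-encounter hotspots from sparse occurrence records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting road-encounter hotspots from sparse occurrence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadhot)
```

## The problem

Road mortality is a leading threat to small, slow-moving wildlife such as
semiaquatic turtles, and mitigation (signage, fencing, passage structures)
can only be installed on a few road segments. The segments worth mitigating
are *road encounter hotspots*: stretches where animals meet the road far
more often than the network background. For rare species, the only
occurrence data available are usually sparse, opportunistically collected
roadside records with severe spatial reporting bias, which defeats naive
density mapping.

`roadhot` implements a three-pronged analysis for exactly this situation:

1. **Matched pseudoabsence modelling.** Each record is paired with a *null
   point* placed 1 km of road distance away on the same road. Because
   reporting effort is approximately constant along a stretch of one road,
   systematic covariate differences between records and their matched nulls
   reflect biology, not observer behavior. Wetland-distance and land-cover
   covariates feed an exhaustive AIC-ranked logistic regression.
2. **Network-constrained kernel density.** Records are linearly referenced
   (tethered) onto road routes and a one-dimensional Epanechnikov kernel
   density is computed along each route. A Monte-Carlo envelope under a
   uniform-placement null flags contiguous significant intervals as
   hotspots, ranked by *cluster strength*.
3. **Least-cost connectivity.** Occupied wetland patches (> 1 ha) become
   core habitat nodes on a resistance surface reclassified from NLCD
   land-cover codes; least-cost paths (LCPs) between cost-adjacent nodes
   predict movement corridors. Hotspots are validated by comparing their
   distances to LCPs against the null points' distances.

The package is written tidyverse-style: tabular inputs and outputs are
tibbles, pipelines compose with the pipe, result objects have `tidy()`,
`glance()` and `autoplot()` methods.

## The models, precisely

**Group contrasts.** For a covariate measured at `n1` record and `n2` null
points, `two_sample_summary()` reports Welch's *t* and Cohen's D on the
pooled SD,

$$D = \frac{\bar{x}_1 - \bar{x}_2}{s_p}, \qquad
  s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2},$$

so printed summary tables (n, mean, SD per group) can be re-analyzed
directly. Paired contrasts use the one-sample $t = \bar{d}/(s_d/\sqrt n)$ on
the matched differences.

**Model selection.** `exhaustive_logistic()` fits a binomial GLM (logit
link) for every subset of up to 20 candidate predictors — from the
intercept-only to the saturated model, $2^p$ fits — and ranks by
$\mathrm{AIC} = 2k - 2\ln L$. Akaike weights are
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$ and models with
$\Delta_i \le 2$ are flagged as equally supported. Complete separation is
handled by a tiny-ridge refit (data augmentation, $\lambda = 10^{-3}$) with
a warning, so no subset is silently dropped. Model accuracy is summarized by
the percent correct in the confident bins ($p \ge 0.75$, $p \le 0.25$) and
Cohen's kappa on the 0.5-dichotomized prediction; the dichotomization
threshold is a package choice, stated because kappa is threshold-dependent.

**Network KDE.** With events at measures $m_i$ on a route of length $L$,
the density at position $s$ is

$$\hat f(s) = \sum_i \frac{1}{M_i h} K\!\left(\frac{s-m_i}{h}\right),
  \qquad K(u) = \tfrac{3}{4}(1-u^2)_+,$$

where $M_i$ renormalizes each kernel by its mass remaining inside $[0, L]$
(edge correction), so the profile integrates to the event count. The
significance threshold at each position is the $(1-\alpha)$ quantile of
profiles from `n_sim` uniform placements of the same number of events;
contiguous exceedance intervals (gaps below one sampling step merged,
intervals without an event dropped) are hotspots. Cluster strength is the
excess mass $\int (\hat f - \text{threshold})_+$ of a hotspot divided by the
network-wide maximum, giving the top hotspot strength 1. The kernel, the 5 m
step, the pointwise envelope and the strength normalization are this
package's choices — the published network-KDE tool this mirrors does not
document its internals — and each sits behind its own function so any piece
can be swapped.

**Connectivity.** The resistance surface maps each NLCD class to an integer
cost per `default_resistance_table()`, a table derived from
landscape-genetic connectivity modelling of Blanding's Turtle; it is used
verbatim, including its initially surprising entries (cultivated crops 2,
emergent herbaceous wetlands 466 — gene flow, not habitat quality, drives
these values). Roads are deliberately absent from the surface: the species
is treated as a road "non-responder" whose movement paths ignore traffic.
Cost distance runs Dijkstra on the 8-connected cell graph with edge weight
$\frac{r_a + r_b}{2}\,\text{cellsize}\,(\sqrt2\ \text{if diagonal})$; node
pairs are selected by cost-weighted Voronoi adjacency (cells allocated to
their cost-nearest node; nodes whose regions share an edge are paired),
and `least_cost_path()` traces the optimal cell path per pair.

**Validation.** Hotspot intervals and null points are compared by distance
to the nearest LCP (Mann-Whitney, with U, a tie-corrected z, and exact
enumeration for tiny samples). Because hotspots are intervals and nulls are
points, a conservative correction re-tests after adding half the mean
hotspot length to every hotspot distance. A complementary statistic asks
what fraction of records falls on road segments crossed by an LCP versus
the fraction of network length those segments occupy.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| tether offset | 10 m | max record-to-road snap distance (georeferencing error + verge records) |
| trim radius | 100 m | roads with no occurrence within this distance are removed (detection-bias control) |
| null offset / separation | 1000 m | matched null placement and minimum road distance from every record |
| buffer radii | 50/100/250 m | covariate scales; 100 m carries the strongest effects |
| KDE bandwidth *h* | 100, 200 m | kernel half-width; hotspot scale of interest |
| envelope level α | 0.005 (pipeline) | pointwise level; see below |
| n_sim | 999 | Monte-Carlo placements per route |
| min node area | 10,000 m² | core wetland patches must exceed 1 ha |
| hotspot buffer / exclusion | 250 m | hotspot land-cover contrast geometry |
| LCP crossing tolerance | 30 m | one raster cell |

The stand-alone `significance_threshold()` defaults to the conventional
α = 0.05, but the pipeline sets 0.005: the envelope is tested at every 5 m
position, and under a uniform null a pointwise 5% level flags about 5% of
network length — dozens of single-record "hotspots" on a realistic network.
One order of magnitude is a deliberately blunt multiplicity correction
(roughly the number of independent positions per route at $h = 200$ is
$L/2h \approx 30$); users wanting exact familywise control can raise
`n_sim` and lower `alpha` further.

## What the synthetic generator emulates — and what it does not

Real georeferenced locations of the study species are sensitive (poaching
risk) and not distributable, so `synth_config()` + `generate_landscape()` /
`generate_road_network()` / `generate_encounters()` create landscapes with
the statistical structure the analysis assumes:

* **Composition**: realized class proportions match the study region's NLCD
  breakdown (37% deciduous forest, 16% hay/pasture, 16% woody wetlands, …)
  to within a cell, via quantile-thresholded smoothed Gaussian noise.
  Classes occupy bands along a wet-to-dry gradient so wetlands adjoin
  forest rather than cropland, the adjacency of a rural lowland landscape.
* **Sampling intensity**: the default 12 × 12 km extent with 16 roads
  (~190 road-km) carries 249 records — about 1.3 records per road-km,
  matching the study's sampled-network density. This ratio controls how
  far matched nulls must wander and therefore the realized effect sizes;
  at desk scale it, not the full 11,000-km network, is the condition worth
  reproducing.
* **Wetland attraction**: background records are placed with weight
  $\exp(-\beta_w d_{\text{wet}} / 100\,\text{m})$, $\beta_w = 0.25$,
  chosen to yield medium standardized contrasts (|D| roughly 0.5–1)
  against matched nulls, the regime reported for the real data.
* **Hotspot structure**: 40% of records arrive as Gaussian clusters
  (SD 50 m along the road) at positions where real least-cost corridors —
  computed between the occupied wetland patches over the default
  resistance surface — cross roads, preferring wetland-adjacent crossings.
  The study attributed 41% of records to its 24 hotspots.
* **Occupancy records**: 54 points inside road-adjacent wetland patches
  over 1 ha stand in for the study's wetland trapping surveys and gate
  core-node selection, mirroring the study's larger occurrence database.

Not emulated: demography, seasonality and sex structure of the records;
traffic volume; reporting-effort gradients between roads; real hydrography
(wetland patches are level sets of a random field). Passing tests therefore
show that the estimators recover planted structure under the stated
conditions — not that any particular real landscape meets those conditions.

## Numerical and design choices

* Distances between points/roads and raster-derived wetland patches are
  exact Euclidean distances to the union of cell squares, not to cell
  centers; patch-to-patch distances use boundary cells only.
* The "distance between opposing wetlands" is read as the minimum
  edge-to-edge distance between the nearest patch on each side of the road.
  It is deliberately *not* `nearest + opposite`: laterally offset patches
  produce a shorter chord, the pattern visible in the published means. A
  side with no wetland within 5 km is censored at 5 km and flagged, and
  censored points are excluded from distance statistics.
* Null-point direction at ±1 km is a seeded coin flip when both directions
  are valid; when neither is, the route is scanned outward in 10 m steps
  and ties at equal distance break toward increasing measure. Along-road
  distance is undefined across routes (the pairing never leaves "the same
  roadway"), the 100 m trim test is inclusive, and coincident null points
  are deduplicated.
* Zonal statistics use the cell-center-in-circle rule; when a buffer is
  smaller than half a cell the containing cell is used.
* NLCD Barren Land is not named in the published five-class consolidation;
  it is mapped to grassland (open, non-forested, non-developed ground).
* Cost-distance edges average the two cell resistances; ties in Dijkstra
  resolve by the graph library's deterministic vertex ordering, so runs are
  reproducible even where multiple optimal paths exist.
* `profile_mass()` integrates with composite Simpson; the profile is
  piecewise quadratic, so mass conservation holds to ~10⁻⁶ per event at a
  0.5 m step (quadrature, not model, error dominates at the 5 m
  operational step).
* All randomness flows through explicit integer seeds; the pipeline derives
  stage seeds from one master seed and stamps every output's manifest.

## Problem sizes used by the test and acceptance suites

The shipped property suites run the pipeline at reduced scale so each suite
completes in minutes on one CPU: kernel recovery and false-positive control
use single 5 km routes (50 and 20 seeded replicates); parameter recovery
uses 9 × 9 km landscapes with 80 records and 50 replicates; the end-to-end
corridor validation uses 6 × 6 km landscapes with 40 records, three planted
clusters and 50 replicates; the cost-distance oracle is exhaustive
relaxation on one hundred 5 × 5 grids. The acceptance script runs the full
default 12 × 12 km configuration once. These sizes are package choices
balancing statistical power against runtime; all thresholds (≥ 90%
recovery, ≥ 80% validation success, false-positive length ≤ α + 0.05) are
stated in the corresponding tests.

## Known limitations

* Kernel mass does not flow across route intersections; densely gridded
  urban networks would need a graph-aware kernel.
* The pointwise Monte-Carlo envelope is not a familywise test; the
  pipeline's α = 0.005 is a pragmatic, not exact, correction.
* Cluster strength reproduces the *ordering* semantics of published
  cluster-strength scores, not their numeric values.
* Cost-weighted Voronoi adjacency can omit pairs a human would draw on
  visual inspection (e.g., nearly-collinear triples), and corridor
  density at small synthetic extents is necessarily higher than in a real
  8000 km² region.
* The GLM stage ignores residual spatial autocorrelation; the 1 km pairing
  design, not a correlation model, is the defense, as in the source
  analysis design.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(synth = synth_config(seed = 42), seed = 42)
res <- run_all(cfg, out_dir = "roadhot-demo")

glance(res$stats$models)   # model ranking summary
res$stats$agreement        # confident-bin accuracy and kappa
res$validation             # hotspot vs null distance to corridors
plot_hotspot_map(res$hotspots$h200, res$network, res$lcps)
```

The README shows the printed output of this exact run.
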