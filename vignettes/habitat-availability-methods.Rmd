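---
title: "Habitat availability from resistance kernels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat availability from resistance kernels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AHAscape)
```

## The problem

Mobile generalist species that inhabit mosaic agricultural landscapes do
not occupy discrete habitat patches, so patch-based availability metrics
(which require delineating habitat) fit them poorly. What such species
experience is *how much area they can reach* from a location, given their
dispersal capacity and the barriers — roads, buildings, water — the
landscape puts in their way. Because infrastructure accumulates over
decades and species respond with a lag, availability must be traced
through time, not read off the current map.

AHAscape turns a categorical land-cover time series into per-pixel
resistance surfaces, evaluates truncated least-cost kernels around a
regular grid of focal points at several dispersal budgets, and normalizes
the reached area into the Amount of Habitat Available,
$AHA_p = a_p / (\pi R^2)$. Downstream modules cluster the AHA
trajectories, test cluster overlap with indicator-species presence, and
fit a presence–absence GLM battery that asks *which year's* availability
best explains today's occurrences.

## Resistance model

Per-pixel crossing costs come from the rank-cost scaling
$C_i = (Rank_i/Rank_{max})^x \cdot C_{max}$:

| parameter | default | meaning |
|---|---|---|
| ranks | lake 2, road 2.5, building 3 | barrier strength relative to the worst class |
| $Rank_{max}$ | 3 | top rank (buildings: hardest to circumvent) |
| $x$ | 4 | contrast: the second-ranked class costs about half the top |
| $C_{max}$ | 500 / pixel | cost of a full crossing of a top-ranked 10 m pixel |
| base cost | 10 / pixel | permeable (open/natural) pixel crossing |
| overrides | road 250, building 500 | published per-class values, used verbatim |

Assumptions worth making explicit:

* **Barriers are semi-permeable.** Every cost is finite; a road can be
  crossed at a price. This is what lets historical availability linger as
  a predictor — species can persist and recolonize across imperfect
  barriers.
* **Permeable classes bypass the formula.** Open land gets the base cost
  directly rather than rank 1 through the formula (which would give 6.17
  per pixel). With 10 m cells and base cost 10, one cost unit equals one
  metre of frictionless movement, so a budget of 1000 units is a 1000 m
  dispersal radius in open land. This keeps budgets interpretable as
  metric dispersal distances; a literal "one unit per open pixel" reading
  is available by setting `baseCostPerPixel = 1`.
* **Printed values beat derived values.** The formula yields 241.13 for
  rank 2.5, while the published per-class table prints 250 for roads. The
  shipped default keeps the printed 250/500 as explicit overrides and the
  formula value is one `resistanceConfig(overrides = numeric())` away.
  The discrepancy is surfaced here rather than silently resolved.

## Kernels and the AHA normalization

Accumulated costs spread from the focal cell by Dijkstra's algorithm over
the 8-connected raster graph with edge weight
$\frac{len}{cs}\cdot\frac{c_{src}+c_{dst}}{2}$, where $len$ is the cell
size orthogonally and $\sqrt2$ times that diagonally. Numerical choices,
each of which an equally defensible alternative exists for, are fixed as
follows:

* **Arithmetic-mean edge costs with $\sqrt2$ diagonal scaling** — the
  standard cost-distance semantics of raster GIS tools.
* **Closed truncation**: cells whose accumulated cost equals the budget
  exactly are included ("within this cost limit").
* **The focal cell costs nothing to occupy**, even on a barrier, so AHA
  is defined for every grid point, urban ones included.
* **Windowing is lossless.** Since every edge costs at least the base
  cost, nothing beyond the frictionless radius is reachable; the search
  runs on a window of that half-width and the tests verify equality with
  the unwindowed run.
* **Area = reached-cell count × cell area.** `kernelToPolygon()` traces
  the boundary rings (outer counter-clockwise, holes clockwise) for
  parity with a polygonization workflow; its signed shoelace area equals
  the cell-count area exactly, which the tests assert.

Under these rules a uniform landscape yields an octagonal reachable set
whose area is $2\sqrt2/\pi \approx 0.90$ of the enclosing disc — the
frictionless AHA plateau. AHA is therefore bounded near 0.9, not 1.0, in
open land; the normalization is kept as $\pi R^2$ because that is how the
metric is defined, and the octagonal deflation is identical across scales
and time steps and so cancels from every comparison the pipeline makes.
A validity band of (0, 1.005] absorbs rasterization slack.

One Dijkstra run at the largest budget serves all budgets of a focal
point (accumulated costs below a smaller budget are unchanged), and focal
points are computed independently — results cannot depend on evaluation
order.

## HMD baseline

The fixed-shape comparison metric is the percentage of road/building
cells in a circular window around each focal cell, one radius per
dispersal distance. The window shape and edge handling are unstated in
the source analyses; we use circles (matching the frictionless kernel's
disc) and clip the denominator at the landscape edge.

## Clustering

Multi-dimensional time-series K-Means under the Euclidean metric is
mathematically plain K-Means on the flattened (time step × budget)
vector, which is how it is implemented. No feature scaling is applied —
AHA is already normalized to be comparable across scales. `stats::kmeans`
is the engine inside an explicit best-of-`nInit` loop (default 10) whose
seeded initializations draw distinct rows as starting centres; every
initialization's WCSS is kept so the "best of" contract is testable, and
the run is reproducible bit-for-bit from the seed.

The cluster count comes from the WCSS elbow, automated as the k with the
maximum discrete second difference of the curve. Visual elbow judgment
cannot be automated faithfully, so a manual `override` argument exists; a
linear WCSS decline has no elbow and falls back to the smallest interior
k with a warning. Spatial clustering (final time step only) and
trajectory clustering are aligned with the Kuhn–Munkres algorithm,
maximizing the points on the mapped diagonal of the confusion table;
surplus clusters of the larger labeling are reported unmatched. No
assignment-problem solver is available among the package's dependencies,
so the $O(k^3)$ shortest-augmenting-path algorithm is implemented here
and verified against brute-force enumeration for $k \le 6$.

## Species validation

* **Permutation test.** Cluster labels are shuffled preserving cluster
  sizes (default 1000 shuffles); a cluster *overlaps* presence if its
  observed presence count is strictly greater than the null count in at
  least 99% of permutations, and *deters* if strictly less in at least
  99%. Strict inequalities against empirical order statistics make the
  test slightly conservative on discrete counts; the calibration test
  (200 simulated datasets) shows both tails within the binomial 99%
  interval of the nominal 1%.
* **GLM battery.** For each metric (AHA, HMD), year, and scale (each
  budget plus the combined "Allscales" model; optional squared terms),
  25 replicates each draw a stratified subsample — 30% of the points at
  50% presence / 50% absence, the device used to thin spatially
  autocorrelated data under a ~20% presence rate — standardize the
  predictors within the subsample, fit a binomial GLM, and record the
  rank AUC (ties counted half) and the effect size. Replicate $r$ of
  every battery cell uses subsampling seed $seed + r - 1$, so AHA and
  HMD see identical subsamples and are directly comparable. Perfect
  separation is flagged and the replicate excluded from aggregates with
  a warning. AUC is computed in-sample on the fitted subsample; no
  held-out split is described for the reference analysis, and the
  battery's purpose is comparison across years and metrics rather than
  honest absolute skill.
* **Effect size.** Reported analyses describe a probability-like effect
  per standard deviation of predictor, centred on 0.5 with >0.5 meaning
  a positive association, but give no formula. The package
  operationalizes it as the inverse logit of the standardized slope:
  exactly 0.5 at $\beta = 0$, strictly increasing, bounded in (0, 1).
  This is the simplest transform with the documented properties, and it
  is stated prominently because it is a package choice, not an inherited
  formula.

## The synthetic-landscape generator

The generator emulates the statistical structure the analysis assumes —
it is the package's study system, not a convenience mock:

* binary road/building rasters at 10 m, road widths 10–50 m (narrow
  widths most common, as in cartographic road-type hierarchies);
* monotone infrastructure growth (never removed), realized by
  representing every road fragment and building cluster as a rectangle
  with an appearance time step, so nestedness holds by construction;
* a static lake mask, including thin water strips between region bands;
* horizontal region bands following the three temporal archetypes of AHA
  change: *cascading* (a moderately gappy road grid whose gaps close
  from the breakpoint onward — half at the breakpoint, the rest one step
  later — plus narrow connector roads and suburban building seeds
  arriving with the densification wave), *saturating high* (one static
  road, a few slow-growing building clusters), and *saturating low*
  (dense road grid and building lattice from the first step). The
  cascading band's collapse is configurational: its HMD changes far less
  than its AHA, which is the property that separates the two metrics
  downstream.
* a species layer: per 100 m cell, presence is Bernoulli with
  $\mathrm{logit}\,p = \alpha + \beta \cdot AHA(t^*)$ taken from the
  nearest focal point at the lag time step $t^*$; quality 0–9 is the
  presence count in the cell's 3×3 neighbourhood, and analysis-block
  presence is "block maximum quality ≥ 1" (high quality ≥ 5).

The intercept $\alpha$ is calibrated so the expected presence rate *at
the analysis points* equals the target prevalence (default 20%, the
study-level rate). Calibrating at the raw cell level instead would
saturate block-level presence — the 3×3 quality smoothing plus the block
maximum turn a 20% cell rate into near-certain block presence — so the
calibration inverts the exact closed-form block-presence probability
under independent Bernoulli cells (solved with `uniroot`), not a
simulation.

What the generator does *not* emulate: realistic urban-growth processes,
cartographic digitization artifacts, spatially autocorrelated species
noise beyond the 3×3 smoothing, topography, or any land-cover class
beyond the four coded ones. Passing tests therefore demonstrate that the
pipeline recovers planted structure of the kind the method targets; they
do not certify performance on real historical maps.

## Fixture sizes and design choices

The documented fixture catalog fixes the problem sizes used throughout
the tests: `tiny` (150×150 cells, 2 years, 2 budgets, 36 focal points;
smoke-scale, with prevalence raised to 35% so a balanced subsample of 36
points is feasible), `three-archetype` (575×300 cells, 4 years, budgets
250/500/1000, 276 points), and `lag-recovery` (500×400 cells, 4 years,
320 points; three cascading bands closing after years 1, 2 and 3 plus
stable bands, species generated at $t^* = $ year 2). These sizes keep a
full run in tens of seconds on one CPU while leaving each effect —
archetype separation, elbow at k = 3, the AUC peak at $t^*$, AHA > HMD —
comfortably clear of its test threshold.

Two fixture-design points deserve note. First, band heights in
`three-archetype` are unequal (the low-stable band is the smallest) and
cascading bands start at the high band's level and end at the low
band's: K-Means elbow detection by maximum second difference reliably
finds k = 3 only when the three trajectory centroids are roughly
equidistant, which is a property of well-separated archetypes, not of
the detector. Second, water strips between bands limit cross-band
kernel leakage, keeping each band's trajectory its own.

## Known limitations

* Rasters are read and written as ESRI ASCII grids (plain text). The
  format carries no CRS; the `crs` field is a free-text identifier and
  no reprojection is attempted.
* Costs are isotropic and single-factor (human modification only); no
  climate, vegetation or elevation resistance, no perceptual ranges or
  stepping-stone behaviour — the kernel is a reachability envelope, not
  a movement model.
* The elbow rule is a heuristic; for real data the override exists and
  should be used with a plotted curve.
* In-sample AUC overstates absolute discrimination; interpret the
  battery comparatively.
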