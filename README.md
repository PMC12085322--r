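# AHAscape

Spatio-temporal habitat availability for mobile generalist species in
human-modified landscapes.

Landscape change is a trajectory, not a snapshot: species often respond to
the landscape of decades ago (extinction debt), so contemporary occurrence
data can be better explained by historical habitat availability than by the
current map. AHAscape implements the **Amount of Habitat Available (AHA)**
metric and the analysis pipeline around it for exactly this question. It is
aimed at landscape ecologists working with categorical land-cover time
series (roads, buildings, lakes, open land) and indicator-species presence
data.

## The metric

Land cover is converted to a per-pixel resistance surface with a rank-cost
formula

```
C_i = (Rank_i / Rank_max)^x * C_max
```

where barrier classes are ranked by how strongly they impede movement
(lake 2, road 2.5, building 3 = Rank_max), the contrast exponent is x = 4,
and C_max = 500 cost units per 10 m pixel. The replication default assigns
the published per-class values (road 250, building 500 per pixel); open and
natural land is fully permeable at the base cost of 10 per pixel, so one
cost unit equals one metre of frictionless movement. From every focal point
of a regular 250 m analysis grid, a truncated cost-distance (Dijkstra)
kernel over the 8-connected raster graph collects the cells reachable
within a dispersal budget (defaults 250, 500, 1000, 2000, 4000 units,
spanning the dispersal capacities of a multi-species guild). With `a_p` the
reached area and `R` the frictionless radius implied by the budget,

```
AHA_p = a_p / (pi * R^2)
```

is a dimensionless availability in (0, 1], comparable across dispersal
scales. Unlike fixed-shape moving-window metrics (the **HMD** —
human-modification density — baseline, also provided), AHA responds to the
*configuration* of barriers, not only their density.

Downstream, the package provides multi-dimensional K-Means clustering of
AHA trajectories (with WCSS elbow selection and Kuhn–Munkres alignment of
two labelings), a permutation test of cluster overlap with species
presence, and a binomial-GLM battery (stratified 50/50 subsampling, rank
AUC, probability-scale effect sizes) that detects which historical year's
AHA best predicts today's species presence. A synthetic-landscape
generator reproduces the temporal archetypes of AHA change (cascading
decline, high-stable, low-stable), so the whole pipeline is testable
without any external data.

## Worked example

```r
library(AHAscape)

fx    <- fixtureScenario("tiny", seed = 1)        # 1.5 km x 1.5 km, 2 years
stack <- generateLandscapeSeries(fx$spec)
grid  <- buildAnalysisGrid(stack, 250)
cube  <- computeAHACube(stack, resistanceConfig(), grid, budgets = c(250, 500))
cube
#> class: AHACube
#> dim: 36 2
#> assays(2): 250 500
#> rownames(36): p0001 p0002 ... p0035 p0036
#> colnames(2): 1992 2012
```

The fixture plants a sparse ("high-stable") band and a densely built
("low-stable") band; mean AHA at the 500-unit budget in 2012 separates
them:

```r
pts  <- analysisPoints(grid)
band <- ifelse(pts$row <= 75, "high-stable", "low-stable")
round(tapply(scaleValues(cube, 500)[, "2012"], band, mean), 3)
#> high-stable  low-stable
#>       0.387       0.026
```

Species presence generated from AHA concentrates in the high band, and the
permutation test recovers that:

```r
quality  <- generateSpeciesQuality(cube, fx$spec)
presence <- alignQualityToGrid(quality, grid)
m    <- fitTsKmeans(cube, k = 2, nInit = 10, seed = 1)
perm <- permutationOverlapTest(clusterLabels(m), presence$presence,
                               nPerm = 1000, seed = 2)
perm@summary[, c("cluster", "size", "observed", "null_mean", "verdict")]
#>   cluster size observed null_mean  verdict
#> 1       1   18        0     8.549   deters
#> 2       2   18       17     8.451 overlaps
```

Cluster 2 (the high-stable band) holds 17 of the 17 presences against a
null expectation of 8.5 — it significantly overlaps species presence at the
99% level, while the built-up cluster significantly deters it.

`runPipeline(list(fixture = "tiny", seed = 1), outdir = "out")` runs the
whole chain (resistance → AHA → HMD → clustering → alignment → permutation
test → GLM battery) and writes CSV/ASCII-grid stage outputs plus a
checksummed JSON manifest; `inst/scripts/aha` is a thin command-line
wrapper over the same functions.

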