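#' @include AllClasses.R kernels.R hmd.R landscape-io.R
NULL

#' Scenario specification for the synthetic-landscape generator
#'
#' Describes a synthetic landscape time series with the statistical
#' structure the analysis assumes: horizontal region bands, each following
#' one temporal archetype of habitat-availability change — `cascading`
#' (moderately gappy road network whose gaps close from the breakpoint time
#' step onward, collapsing AHA with little density change),
#' `saturating_high` (sparse infrastructure, AHA high and stable) and
#' `saturating_low` (dense road grid and building clusters from the first
#' time step, AHA low and stable). Roads are straight segments rasterized
#' at class-specific widths of 10-50 m (1-5 cells, narrow widths most
#' common); buildings grow around seed clusters; lakes are static,
#' including optional thin water barriers between bands. Infrastructure is
#' never removed, so the road-and-building masks are nested over time.
#'
#' The species link draws indicator presence on a 100 m grid from a
#' logistic model on AHA at a historical time step `tStar`, with the
#' intercept calibrated so that the presence rate at the analysis points is
#' about `prevalence` (default 20%).
#'
#' @param nRows,nCols landscape size in fine cells.
#' @param cellSize fine cell size in metres (default 10).
#' @param years time-step labels (default the eight study years 1899-2012).
#' @param bands data.frame with columns `archetype` (one of `cascading`,
#'   `saturating_high`, `saturating_low`) and `breakpoint` (time-step index
#'   at which a cascading band's road gaps start closing; `NA` otherwise).
#'   An optional `height` column fixes each band's height in cells
#'   (default: equal split). Bands are horizontal, top to bottom.
#' @param roadWidths possible road widths in cells with sampling weights
#'   favouring narrow roads.
#' @param buildingGrowth building cluster radius growth in cells per time
#'   step.
#' @param lakeBarriers paint static 4-cell water strips between bands
#'   (limits cross-band kernel leakage, as large rivers do).
#' @param species list with `tStar` (time-step index the presence pattern
#'   is generated from), `budget` (dispersal budget whose AHA drives
#'   presence), `beta` (logistic slope per AHA unit) and `prevalence`
#'   (target presence rate at the analysis points).
#' @param seed master seed; all generation is reproducible from it.
#' @return list of class `ScenarioSpec`.
#' @export
scenarioSpec <- function(nRows = 360, nCols = 360, cellSize = 10,
                         years = c("1899", "1918", "1933", "1959", "1970",
                                   "1978", "1992", "2012"),
                         bands = data.frame(
                           archetype = c("cascading", "saturating_high",
                                         "saturating_low"),
                           breakpoint = c(4L, NA, NA)),
                         roadWidths = c(1L, 2L, 3L, 4L, 5L),
                         buildingGrowth = 0.25,
                         lakeBarriers = TRUE,
                         species = list(tStar = 3L, budget = 1000,
                                        beta = 8, prevalence = 0.2),
                         seed = 1L) {
  ok <- c("cascading", "saturating_high", "saturating_low")
  if (!all(bands$archetype %in% ok))
    stop("unknown archetype(s): ",
         paste(setdiff(bands$archetype, ok), collapse = ", "))
  casc <- bands$archetype == "cascading"
  if (any(casc & (is.na(bands$breakpoint) | bands$breakpoint < 2 |
                  bands$breakpoint > length(years))))
    stop("cascading bands need a breakpoint in 2..length(years)")
  stopifnot(species$prevalence > 0, species$prevalence < 1,
            all(roadWidths >= 1L), all(roadWidths <= 5L))
  structure(list(nRows = as.integer(nRows), nCols = as.integer(nCols),
                 cellSize = cellSize, years = as.character(years),
                 bands = bands, roadWidths = roadWidths,
                 buildingGrowth = buildingGrowth, lakeBarriers = lakeBarriers,
                 species = species, seed = as.integer(seed)),
            class = "ScenarioSpec")
}

## weights favouring narrow (and usually less busy) roads
.widthProbs <- function(widths) {
  p <- c(0.35, 0.3, 0.15, 0.1, 0.1)[widths]
  p / sum(p)
}

## All infrastructure is represented as rectangles with an "appear" time
## step, so cumulative union over time is monotone by construction. A
## gappy cascading road is its always-present parts (appear = 1) plus its
## gap stretches appearing at their closing time step.
.bandPlan <- function(archetype, r0, r1, nc, breakpoint, nT, widths,
                      growth) {
  rects <- list()
  blds <- list()
  addRect <- function(rr0, rr1, cc0, cc1, appear) {
    rects[[length(rects) + 1L]] <<- c(r0 = rr0, r1 = rr1, c0 = cc0,
                                      c1 = cc1, appear = appear)
  }
  addBld <- function(cr, cc, rad, appear) {
    blds[[length(blds) + 1L]] <<- c(cr = cr, cc = cc, rad = rad,
                                    appear = appear)
  }
  u <- r1 - r0 + 1L
  wsample <- function(maxw) {
    w <- widths[widths <= maxw]
    sample(w, 1L, prob = .widthProbs(w))
  }
  gappyRoad <- function(vertical, pos, w, lo, hi) {
    ## gap stretches of 8 cells every ~16 cells close at the breakpoint or
    ## the following step ("increasingly closed over time")
    gaps <- seq(lo + 6L + sample(0:4, 1L), hi - 8L, by = 16L)
    for (i in seq_along(gaps)) {
      g0 <- gaps[i]; g1 <- min(gaps[i] + 7L, hi)
      closeAt <- min(breakpoint + (i %% 2L), nT)
      if (vertical) addRect(g0, g1, pos, pos + w - 1L, closeAt)
      else addRect(pos, pos + w - 1L, g0, g1, closeAt)
    }
    ## always-present parts: full span minus gaps
    keep <- rep(TRUE, hi - lo + 1L)
    for (i in seq_along(gaps))
      keep[seq(gaps[i], min(gaps[i] + 7L, hi)) - lo + 1L] <- FALSE
    runs <- rle(keep)
    at <- lo
    for (j in seq_along(runs$lengths)) {
      if (runs$values[j]) {
        if (vertical) addRect(at, at + runs$lengths[j] - 1L, pos,
                              pos + w - 1L, 1L)
        else addRect(pos, pos + w - 1L, at, at + runs$lengths[j] - 1L, 1L)
      }
      at <- at + runs$lengths[j]
    }
  }
  if (archetype == "saturating_high") {
    pos <- r0 + u %/% 2L + sample(-4:4, 1L)
    w <- wsample(2L)
    addRect(pos, pos + w - 1L, 1L, nc, 1L)
    for (i in seq_len(max(2L, round(u * nc / 25000))))
      addBld(sample(seq(r0 + 3L, r1 - 3L), 1L),
             sample(seq(4L, nc - 4L), 1L), 1, 1L)
  } else if (archetype == "saturating_low") {
    for (p in seq(8L, nc - 2L, by = 16L))
      addRect(r0, r1, p + sample(-2:2, 1L), p + wsample(2L) - 1L, 1L)
    for (p in seq(r0 + 6L, r1 - 2L, by = 16L))
      addRect(p + sample(-2:2, 1L), p + wsample(2L) - 1L, 1L, nc, 1L)
    ctrs <- expand.grid(cr = seq(r0 + 4L, r1 - 4L, by = 12L),
                        cc = seq(5L, nc - 5L, by = 12L))
    for (i in seq_len(nrow(ctrs)))
      addBld(ctrs$cr[i] + sample(-2:2, 1L), ctrs$cc[i] + sample(-2:2, 1L),
             2, 1L)
  } else {  # cascading
    for (p in seq(12L, nc - 4L, by = 24L))
      gappyRoad(TRUE, p + sample(-2:2, 1L), wsample(2L), r0, r1)
    for (p in seq(r0 + 12L, r1 - 4L, by = 24L))
      gappyRoad(FALSE, p + sample(-2:2, 1L), wsample(2L), 1L, nc)
    ## post-breakpoint densification: narrow connector roads halving the
    ## compartments, completing the configurational collapse
    late <- min(breakpoint + 1L, nT)
    for (p in seq(24L, nc - 4L, by = 24L)) {
      pj <- p + sample(-2:2, 1L)
      addRect(r0, r1, pj, pj, late)
    }
    for (p in seq(r0 + 24L, r1 - 4L, by = 24L)) {
      pj <- p + sample(-2:2, 1L)
      addRect(pj, pj, 1L, nc, late)
    }
    ## suburban building clusters arrive with the densification wave
    ctrs <- expand.grid(cr = seq(r0 + 8L, r1 - 8L, by = 36L),
                        cc = seq(10L, nc - 10L, by = 36L))
    for (i in seq_len(nrow(ctrs)))
      addBld(ctrs$cr[i] + sample(-3:3, 1L), ctrs$cc[i] + sample(-3:3, 1L),
             1, breakpoint)
  }
  list(rects = do.call(rbind, rects),
       buildings = if (length(blds)) do.call(rbind, blds) else NULL)
}

#' Generate a synthetic land-cover time series
#'
#' Realizes a [scenarioSpec()] into a [LandcoverStack-class]: per band,
#' road rectangles and growing building clusters with appearance time
#' steps; per time step, the cumulative union of everything that has
#' appeared. Lakes (band-separating strips and one small water body) are
#' static and override other classes, buildings override roads.
#'
#' @param spec a [scenarioSpec()].
#' @return a [LandcoverStack-class].
#' @export
generateLandscapeSeries <- function(spec) {
  stopifnot(inherits(spec, "ScenarioSpec"))
  set.seed(spec$seed)
  nr <- spec$nRows; nc <- spec$nCols
  nT <- length(spec$years)
  nb <- nrow(spec$bands)
  edges <- if (!is.null(spec$bands$height)) {
    if (sum(spec$bands$height) != nr)
      stop("band heights must sum to nRows")
    cumsum(c(0L, spec$bands$height))
  } else round(seq(0L, nr, length.out = nb + 1L))
  lake <- matrix(FALSE, nr, nc)
  if (spec$lakeBarriers && nb > 1L) {
    for (e in edges[-c(1L, nb + 1L)])
      lake[max(1L, e - 3L):min(nr, e + 4L), ] <- TRUE
  }
  ## one small static water body in the first band
  cy <- sample(seq(edges[1L] + 15L, max(edges[1L] + 16L, edges[2L] - 15L)), 1L)
  cx <- sample(seq(15L, nc - 15L), 1L)
  ii <- outer(seq_len(nr), rep(1L, nc)) ; jj <- outer(rep(1L, nr), seq_len(nc))
  lake[((ii - cy) / 8)^2 + ((jj - cx) / 12)^2 <= 1] <- TRUE

  allRects <- list(); allBlds <- list()
  for (b in seq_len(nb)) {
    plan <- .bandPlan(spec$bands$archetype[b], edges[b] + 1L, edges[b + 1L],
                      nc, spec$bands$breakpoint[b], nT, spec$roadWidths,
                      spec$buildingGrowth)
    allRects[[b]] <- plan$rects
    allBlds[[b]] <- plan$buildings
  }
  rects <- do.call(rbind, allRects)
  blds <- do.call(rbind, allBlds)

  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  layers <- vector("list", nT)
  for (t in seq_len(nT)) {
    road <- matrix(FALSE, nr, nc)
    act <- rects[rects[, "appear"] <= t, , drop = FALSE]
    for (i in seq_len(nrow(act))) {
      r <- act[i, ]
      road[clamp(r["r0"], 1L, nr):clamp(r["r1"], 1L, nr),
           clamp(r["c0"], 1L, nc):clamp(r["c1"], 1L, nc)] <- TRUE
    }
    bld <- matrix(FALSE, nr, nc)
    actb <- blds[blds[, "appear"] <= t, , drop = FALSE]
    for (i in seq_len(nrow(actb))) {
      bb <- actb[i, ]
      rad <- floor(bb["rad"] + spec$buildingGrowth * (t - bb["appear"]))
      bld[clamp(bb["cr"] - rad, 1L, nr):clamp(bb["cr"] + rad, 1L, nr),
          clamp(bb["cc"] - rad, 1L, nc):clamp(bb["cc"] + rad, 1L, nc)] <- TRUE
    }
    lay <- matrix(0L, nr, nc)
    lay[road] <- 1L
    lay[bld] <- 2L
    lay[lake] <- 3L
    layers[[t]] <- lay
  }
  LandcoverStack(grid = GridSpec(nr, nc, cellSize = spec$cellSize),
                 years = spec$years, layers = layers)
}

#' Generate a species-quality raster linked to historical AHA
#'
#' Draws indicator-species presence per 100 m cell from a logistic model on
#' the AHA of the nearest focal point at the scenario's lag time step
#' `tStar`, then aggregates presence into the 0-9 quality scale as the
#' count of presence cells in each cell's 3 x 3 neighbourhood. The
#' intercept is calibrated — exactly, from the closed-form probability that
#' an analysis block contains at least one presence-influencing cell — so
#' that the expected presence rate at the analysis points equals the
#' scenario's target prevalence.
#'
#' @param cube an [AHACube-class] containing the lag time step.
#' @param spec the [scenarioSpec()] (for the species link and seed).
#' @return a [SpeciesQualityGrid-class].
#' @export
generateSpeciesQuality <- function(cube, spec) {
  sp <- spec$species
  tStar <- sp$tStar
  if (is.character(tStar)) tStar <- match(tStar, colnames(cube))
  if (is.na(tStar) || tStar < 1L || tStar > ncol(cube))
    stop("domain error: lag time step tStar not in the cube")
  gi <- S4Vectors::metadata(cube)$gridInfo
  spacing <- S4Vectors::metadata(cube)$spacing
  if (is.null(gi)) stop("cube lacks gridInfo metadata")
  aha <- scaleValues(cube, sp$budget)[, tStar]
  rd <- SummarizedExperiment::rowData(cube)

  qcs <- 100
  nrc <- as.integer(floor(gi$nRows * gi$cellSize / qcs))
  ncc <- as.integer(floor(gi$nCols * gi$cellSize / qcs))
  if (nrc < 3L || ncc < 3L) stop("landscape too small for a 100 m quality grid")

  ## nearest focal point of each coarse cell, via analysis-block membership
  br <- as.integer(floor((gi$originY - rd$y) / spacing)) + 1L
  bc <- as.integer(floor((rd$x - gi$originX) / spacing)) + 1L
  pidx <- matrix(NA_integer_, max(br), max(bc))
  pidx[cbind(br, bc)] <- seq_along(aha)
  ccy <- gi$originY - (seq_len(nrc) - 0.5) * qcs
  ccx <- gi$originX + (seq_len(ncc) - 0.5) * qcs
  cbr <- pmin(pmax(as.integer(floor((gi$originY - ccy) / spacing)) + 1L, 1L),
              nrow(pidx))
  cbc <- pmin(pmax(as.integer(floor((ccx - gi$originX) / spacing)) + 1L, 1L),
              ncol(pidx))
  ahaCell <- matrix(NA_real_, nrc, ncc)
  for (i in seq_len(nrc)) ahaCell[i, ] <- aha[pidx[cbr[i], cbc]]
  if (anyNA(ahaCell)) stop("internal error: coarse cell without focal point")

  ## intercept calibration at the analysis-point level: a block is a
  ## presence point iff any 100 m cell whose 3x3 neighbourhood intersects
  ## the block is a presence cell
  cellsPerBlock <- spacing / qcs
  blockCells <- function(b, nMax) {
    lo <- max(1L, as.integer(floor((b - 1L) * cellsPerBlock)) + 1L - 1L)
    hi <- min(nMax, as.integer(ceiling(b * cellsPerBlock)) + 1L)
    lo:hi
  }
  blockSets <- lapply(seq_along(aha), function(p) {
    expand.grid(i = blockCells(br[p], nrc), j = blockCells(bc[p], ncc))
  })
  target <- sp$prevalence
  f <- function(a) {
    pm <- stats::plogis(a + sp$beta * ahaCell)
    mean(vapply(blockSets, function(s)
      1 - prod(1 - pm[cbind(s$i, s$j)]), numeric(1))) - target
  }
  alpha <- stats::uniroot(f, lower = -50, upper = 30, tol = 1e-10)$root

  set.seed(spec$seed + 104729L)  # fixed offset: species draw stream
  pres <- matrix(stats::rbinom(nrc * ncc, 1L,
                               stats::plogis(alpha + sp$beta * ahaCell)),
                 nrc, ncc)
  q <- matrix(0L, nrc, ncc)
  for (di in -1:1) for (dj in -1:1) {
    ri <- pmin(pmax(seq_len(nrc) + di, 1L), nrc)
    rj <- pmin(pmax(seq_len(ncc) + dj, 1L), ncc)
    valid_i <- seq_len(nrc) + di >= 1L & seq_len(nrc) + di <= nrc
    valid_j <- seq_len(ncc) + dj >= 1L & seq_len(ncc) + dj <= ncc
    add <- matrix(0L, nrc, ncc)
    add[valid_i, valid_j] <- pres[seq_len(nrc)[valid_i] + di,
                                  seq_len(ncc)[valid_j] + dj]
    q <- q + add
  }
  SpeciesQualityGrid(
    GridSpec(nrc, ncc, cellSize = qcs, originX = gi$originX,
             originY = gi$originY, crs = gi$crs),
    q)
}

#' Fixture catalog
#'
#' Named, documented synthetic scenarios used throughout the test suite and
#' the worked examples:
#' \describe{
#'   \item{tiny}{150 x 150 cells, 2 time steps, 2 budgets (250, 500); a
#'     high-stable and a low-stable band, species prevalence raised to 35%
#'     so the balanced subsample works at 36 points. Runs end-to-end in
#'     seconds.}
#'   \item{three-archetype}{360 x 360 cells, 4 time steps, budgets 250,
#'     500, 1000; one band per temporal archetype. Trajectory clustering
#'     recovers the three planted groups.}
#'   \item{lag-recovery}{500 x 400 cells, 4 time steps, budgets 250, 500,
#'     1000; cascading bands whose road gaps close after time steps 2, 3
#'     and 4 plus stable bands, with presence generated from AHA at time
#'     step 2 — the GLM battery's AUC peaks at the generating year.}
#' }
#'
#' @param name fixture name.
#' @param seed master seed (default 1).
#' @return list with elements `spec` (a [scenarioSpec()]), `budgets` and
#'   `spacing`.
#' @export
fixtureScenario <- function(name = c("tiny", "three-archetype",
                                     "lag-recovery"), seed = 1L) {
  name <- match.arg(name)
  if (name == "tiny") {
    ## smoke fixture: prevalence raised above the study's 20% so the
    ## stratified subsample is feasible at 36 analysis points
    list(spec = scenarioSpec(
           nRows = 150L, nCols = 150L, years = c("1992", "2012"),
           bands = data.frame(archetype = c("saturating_high",
                                            "saturating_low"),
                              breakpoint = c(NA, NA)),
           species = list(tStar = 1L, budget = 500, beta = 6,
                          prevalence = 0.35),
           seed = seed),
         budgets = c(250, 500), spacing = 250)
  } else if (name == "three-archetype") {
    list(spec = scenarioSpec(
           nRows = 575L, nCols = 300L,
           years = c("1899", "1933", "1970", "2012"),
           bands = data.frame(archetype = c("cascading", "saturating_high",
                                            "saturating_low"),
                              breakpoint = c(3L, NA, NA),
                              height = c(250L, 250L, 75L)),
           species = list(tStar = 2L, budget = 1000, beta = 8,
                          prevalence = 0.2),
           seed = seed),
         budgets = c(250, 500, 1000), spacing = 250)
  } else {
    list(spec = scenarioSpec(
           nRows = 500L, nCols = 400L,
           years = c("1899", "1933", "1970", "2012"),
           bands = data.frame(
             archetype = c("saturating_high", "cascading", "cascading",
                           "cascading", "saturating_low"),
             breakpoint = c(NA, 2L, 3L, 4L, NA)),
           species = list(tStar = 2L, budget = 1000, beta = 10,
                          prevalence = 0.2),
           seed = seed),
         budgets = c(250, 500, 1000), spacing = 250)
  }
}

#' Write a fixture bundle to disk
#'
#' Generates a catalog fixture ([fixtureScenario()]) and writes its
#' land-cover rasters, species-quality raster, a pipeline configuration and
#' the long-format AHA summary into a directory.
#'
#' @param name fixture name from the catalog.
#' @param dir output directory.
#' @param seed master seed.
#' @return (invisibly) list with the written `paths` and the objects
#'   (`stack`, `cube`, `quality`, `grid`).
#' @export
makeFixtureBundle <- function(name, dir, seed = 1L) {
  fx <- fixtureScenario(name, seed)
  stack <- generateLandscapeSeries(fx$spec)
  grid <- buildAnalysisGrid(stack, fx$spacing)
  cube <- computeAHACube(stack, resistanceConfig(), grid, fx$budgets)
  quality <- generateSpeciesQuality(cube, fx$spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lcPaths <- writeLandcoverStack(stack, dir)
  qPath <- file.path(dir, "species_quality.asc")
  writeAsciiGrid(quality@quality, quality@grid, qPath)
  ahaPath <- file.path(dir, "aha_long.csv")
  utils::write.csv(cubeToLong(cube), ahaPath, row.names = FALSE)
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    seed = fx$spec$seed,
    landcover = list(years = as.list(stack@years),
                     paths = as.list(unname(lcPaths))),
    species = qPath,
    spacing = fx$spacing,
    budgets = as.list(fx$budgets),
    clustering = list(kRange = c(1L, 8L), nInit = 10L),
    validation = list(nPerm = 1000L, confidence = 0.99, fraction = 0.3,
                      balance = 0.5, reps = 25L, degree = 1L)
  ), cfgPath)
  invisible(list(paths = c(lcPaths, species = qPath, aha = ahaPath,
                           config = cfgPath),
                 stack = stack, cube = cube, quality = quality, grid = grid))
}
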