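#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

## Land-cover class codes used throughout the package.
.LC_CODES <- c(open = 0L, road = 1L, building = 2L, lake = 3L)

#' GridSpec: geometry of a raster grid
#'
#' Describes the geometry of a regular raster grid. The origin is the
#' top-left corner of the top-left cell; cells are half-open squares
#' \eqn{[x, x + cs) \times (y - cs, y]} indexed row-major from the top-left,
#' with 1-based (row, col) indices as usual in R. All coordinates are in map
#' units (metres).
#'
#' @slot originX,originY numeric map coordinates of the grid origin (top-left
#'   corner of the top-left cell).
#' @slot cellSize numeric cell edge length in metres (fine grids default to
#'   10 m, the species-quality grid to 100 m).
#' @slot nRows,nCols integer grid dimensions.
#' @slot crs character free-text identifier of the coordinate reference
#'   system (no reprojection is performed).
#'
#' @examples
#' GridSpec(nRows = 100, nCols = 100, cellSize = 10)
#' @export
setClass("GridSpec",
  representation(
    originX = "numeric", originY = "numeric", cellSize = "numeric",
    nRows = "integer", nCols = "integer", crs = "character"
  ),
  prototype(originX = 0, originY = 0, cellSize = 10, nRows = 1L, nCols = 1L,
            crs = "local")
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param nRows,nCols grid dimensions.
#' @param cellSize cell edge length in metres.
#' @param originX,originY map coordinates of the top-left corner.
#' @param crs coordinate-reference-system identifier (free text).
#' @rdname GridSpec-class
#' @export
GridSpec <- function(nRows, nCols, cellSize = 10, originX = 0,
                     originY = nRows * cellSize, crs = "local") {
  new("GridSpec", originX = originX, originY = originY, cellSize = cellSize,
      nRows = as.integer(nRows), nCols = as.integer(nCols), crs = crs)
}

#' LandcoverStack: coded land-cover rasters over a time series
#'
#' Holds one coded land-cover raster per time step on a common fine grid.
#' Codes are \code{0 = open}, \code{1 = road}, \code{2 = building},
#' \code{3 = lake}. Lakes are taken from the most recent data and applied
#' uniformly, so the lake mask must be identical across all time steps.
#'
#' @slot grid a [GridSpec-class].
#' @slot years character vector of time-step labels, in chronological order.
#' @slot layers list of integer matrices (one per time step), dimensions
#'   matching \code{grid}.
#' @slot classCodes named integer vector mapping class names to codes.
#'
#' @export
setClass("LandcoverStack",
  representation(grid = "GridSpec", years = "character", layers = "list",
                 classCodes = "integer")
)

setValidity("LandcoverStack", function(object) {
  msg <- character()
  g <- object@grid
  if (length(object@layers) != length(object@years))
    msg <- c(msg, "one layer per time step required")
  known <- object@classCodes
  for (t in seq_along(object@layers)) {
    lay <- object@layers[[t]]
    if (!is.matrix(lay) || nrow(lay) != g@nRows || ncol(lay) != g@nCols) {
      msg <- c(msg, sprintf("layer %d does not match the grid dimensions", t))
      next
    }
    bad <- which(!(lay %in% known))
    if (length(bad)) {
      i <- bad[1L]
      msg <- c(msg, sprintf(
        "layer %d (%s) holds unknown class code %s at cell (row %d, col %d)",
        t, object@years[t], lay[i],
        (i - 1L) %% nrow(lay) + 1L, (i - 1L) %/% nrow(lay) + 1L))
    }
  }
  if (length(object@layers) > 1L && "lake" %in% names(known)) {
    lk <- known[["lake"]]
    m1 <- object@layers[[1L]] == lk
    for (t in seq_along(object@layers)[-1L]) {
      if (!identical(m1, object@layers[[t]] == lk)) {
        msg <- c(msg, sprintf("lake mask differs between time steps 1 and %d", t))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param grid a [GridSpec-class].
#' @param years character vector of time-step labels.
#' @param layers list of integer matrices, one per time step.
#' @param classCodes named integer vector of class codes.
#' @rdname LandcoverStack-class
#' @export
LandcoverStack <- function(grid, years, layers, classCodes = .LC_CODES) {
  layers <- lapply(layers, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  new("LandcoverStack", grid = grid, years = as.character(years),
      layers = layers, classCodes = classCodes)
}

#' ResistanceSurface: per-pixel traversal costs
#'
#' A raster of per-pixel crossing costs (cost units per full orthogonal
#' pixel crossing) derived from a coded land-cover layer. Barriers are
#' semi-permeable: every cost is finite, and permeable cells carry the base
#' cost.
#'
#' @slot grid a [GridSpec-class].
#' @slot cost numeric matrix of per-pixel crossing costs.
#' @slot year time-step label the surface belongs to.
#'
#' @export
setClass("ResistanceSurface",
  representation(grid = "GridSpec", cost = "matrix", year = "character")
)

setValidity("ResistanceSurface", function(object) {
  g <- object@grid
  if (nrow(object@cost) != g@nRows || ncol(object@cost) != g@nCols)
    return("cost matrix does not match the grid dimensions")
  if (any(!is.finite(object@cost)))
    return("costs must be finite (barriers are semi-permeable)")
  if (any(object@cost <= 0))
    return("costs must be positive")
  TRUE
})

#' SpeciesQualityGrid: coarse landscape-quality raster
#'
#' Integer quality values 0-9 on a coarse (default 100 m) grid. A value of 1
#' records indicator-species presence in one cell of a 3 x 3 neighbourhood,
#' 9 presence in all nine; values of 5 or above mark high-quality areas.
#'
#' @slot grid a [GridSpec-class] (coarse).
#' @slot quality integer matrix with values in 0-9.
#'
#' @export
setClass("SpeciesQualityGrid",
  representation(grid = "GridSpec", quality = "matrix")
)

setValidity("SpeciesQualityGrid", function(object) {
  g <- object@grid
  if (nrow(object@quality) != g@nRows || ncol(object@quality) != g@nCols)
    return("quality matrix does not match the grid dimensions")
  if (any(object@quality < 0L | object@quality > 9L))
    return("quality values must lie in 0..9")
  TRUE
})

#' @param grid a [GridSpec-class].
#' @param quality integer matrix of 0-9 quality values.
#' @rdname SpeciesQualityGrid-class
#' @export
SpeciesQualityGrid <- function(grid, quality) {
  storage.mode(quality) <- "integer"
  new("SpeciesQualityGrid", grid = grid, quality = quality)
}

#' AnalysisGrid: regular lattice of focal points
#'
#' The focal points at which AHA and HMD are evaluated: one point per
#' \code{spacing} x \code{spacing} block fully inside the landscape extent,
#' placed at the centre of the fine cell nearest the block centroid (the
#' kernel source must be a single fine cell).
#'
#' @slot spacing block edge length in metres (default 250).
#' @slot points data.frame with columns \code{point_id}, \code{x}, \code{y}
#'   (map coordinates of the focal cell centre), \code{row}, \code{col}
#'   (fine-grid index of the focal cell), \code{block_row}, \code{block_col}.
#' @slot grid the fine [GridSpec-class] the points index into.
#'
#' @export
setClass("AnalysisGrid",
  representation(spacing = "numeric", points = "data.frame", grid = "GridSpec")
)

setValidity("AnalysisGrid", function(object) {
  need <- c("point_id", "x", "y", "row", "col")
  if (!all(need %in% names(object@points)))
    return(sprintf("points must have columns %s", paste(need, collapse = ", ")))
  if (object@spacing <= 0) return("spacing must be positive")
  TRUE
})

#' KernelResult: one truncated cost-distance kernel
#'
#' The set of fine cells reachable from a focal cell within a dispersal
#' budget, together with the accumulated-cost window the Dijkstra search was
#' run on. \code{aP} is the reached area in square metres
#' (\code{cells * cellSize^2}).
#'
#' @slot focalRow,focalCol fine-grid index of the focal cell.
#' @slot budget dispersal budget in cost units.
#' @slot radiusM frictionless-range radius R in metres implied by the budget.
#' @slot acc numeric matrix of accumulated costs over the search window
#'   (\code{Inf} where the budget was exceeded).
#' @slot reached logical matrix, \code{acc <= budget}.
#' @slot rowOffset,colOffset full-grid index of the window's top-left cell,
#'   minus one (so window row r is full-grid row \code{rowOffset + r}).
#' @slot cellSize fine cell size in metres.
#' @slot aP reached area in m^2.
#'
#' @export
setClass("KernelResult",
  representation(
    focalRow = "integer", focalCol = "integer", budget = "numeric",
    radiusM = "numeric", acc = "matrix", reached = "matrix",
    rowOffset = "integer", colOffset = "integer", cellSize = "numeric",
    aP = "numeric"
  )
)

#' AHACube and HMDCube: focal point x time step x scale arrays
#'
#' Both cubes extend \linkS4class{SummarizedExperiment}: rows are focal
#' points (with \code{rowData} columns \code{point_id}, \code{x}, \code{y}),
#' columns are time steps, and there is one assay per dispersal budget
#' (AHA, dimensionless in (0, 1] up to rasterization slack) or per window
#' radius (HMD, percent in [0, 100]). Metadata records budgets, implied
#' radii, and the resistance configuration used.
#'
#' @aliases AHACube-class HMDCube-class
#' @name AHACube-class
#' @exportClass AHACube
setClass("AHACube", contains = "SummarizedExperiment")

#' @name AHACube-class
#' @exportClass HMDCube
setClass("HMDCube", contains = "SummarizedExperiment")

setValidity("AHACube", function(object) {
  for (a in SummarizedExperiment::assayNames(object)) {
    v <- SummarizedExperiment::assay(object, a)
    if (any(!is.finite(v))) return(sprintf("assay %s holds non-finite values", a))
    if (any(v <= 0 | v > 1.005))
      return(sprintf("assay %s outside (0, 1.005]", a))
  }
  TRUE
})

setValidity("HMDCube", function(object) {
  for (a in SummarizedExperiment::assayNames(object)) {
    v <- SummarizedExperiment::assay(object, a)
    if (any(!is.finite(v)) || any(v < 0 | v > 100))
      return(sprintf("assay %s outside [0, 100]", a))
  }
  TRUE
})

#' ClusterModel: fitted K-Means model for AHA profiles
#'
#' Result of best-of-\code{nInit} K-Means on flattened
#' (time step x budget) AHA features (time-series mode) or on a single
#' time step across budgets (spatial mode).
#'
#' @slot k number of clusters.
#' @slot centroids k x n_features matrix.
#' @slot labels integer cluster id per focal point (1..k).
#' @slot wcss within-cluster sum of squared Euclidean distances (best init).
#' @slot initWcss WCSS achieved by each initialization tried.
#' @slot seed,nInit reproducibility record.
#' @slot mode "timeseries" or "spatial".
#' @slot featureYears,featureBudgets labels of the flattened feature columns.
#'
#' @export
setClass("ClusterModel",
  representation(
    k = "integer", centroids = "matrix", labels = "integer",
    wcss = "numeric", initWcss = "numeric", seed = "integer",
    nInit = "integer", mode = "character",
    featureYears = "character", featureBudgets = "numeric"
  )
)

setValidity("ClusterModel", function(object) {
  if (nrow(object@centroids) != object@k)
    return("centroids must have k rows")
  if (any(object@labels < 1L | object@labels > object@k))
    return("labels must lie in 1..k")
  if (object@wcss < 0) return("wcss must be >= 0")
  TRUE
})

#' AlignmentResult: optimal correspondence between two labelings
#'
#' Hungarian-algorithm alignment of two cluster labelings over the same
#' point set. \code{totalCost} is the number of points not on the mapped
#' diagonal of the confusion table, i.e. points whose pair of labels is not
#' a matched pair.
#'
#' @slot mapping data.frame with columns \code{a}, \code{b}, \code{overlap}:
#'   the matched label pairs and their shared point counts.
#' @slot unmatched labels of the larger labeling with no counterpart.
#' @slot confusion |A| x |B| contingency table of shared points.
#' @slot totalCost number of points off the mapped diagonal.
#'
#' @export
setClass("AlignmentResult",
  representation(mapping = "data.frame", unmatched = "character",
                 confusion = "matrix", totalCost = "numeric")
)

#' PermutationResult: cluster-presence overlap test
#'
#' Per-cluster observed presence counts against a null distribution obtained
#' by shuffling cluster labels while preserving cluster sizes. A cluster
#' significantly overlaps presence if its observed count exceeds the null in
#' at least \code{confidence} of the permutations, and significantly deters
#' if it falls below the null in at least \code{confidence} of them.
#'
#' @slot summary data.frame with columns \code{cluster}, \code{size},
#'   \code{observed}, \code{null_mean}, \code{frac_greater},
#'   \code{frac_less}, \code{verdict}.
#' @slot null k x nPerm matrix of permuted presence counts.
#' @slot nPerm,confidence,seed test parameters.
#'
#' @export
setClass("PermutationResult",
  representation(summary = "data.frame", null = "matrix", nPerm = "integer",
                 confidence = "numeric", seed = "integer")
)
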