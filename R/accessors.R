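#' @include AllClasses.R
NULL

#' Accessors for AHAscape objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an AHAscape object.
#' @param ... passed to methods.
#' @return `gridSpec` returns the [GridSpec-class]; `stackYears` the
#'   time-step labels; `landcoverLayer` one coded matrix; `classCodes` the
#'   named code vector; `costValues` the cost matrix; `qualityValues` the
#'   quality matrix; `analysisPoints` the focal-point data.frame;
#'   `dispersalBudgets` the budget vector of a cube; `scaleValues` the
#'   point x timestep matrix of one assay.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname accessors
#' @export
setGeneric("stackYears", function(x) standardGeneric("stackYears"))

#' @rdname accessors
#' @param year a time-step label or index.
#' @export
setGeneric("landcoverLayer", function(x, year) standardGeneric("landcoverLayer"))

#' @rdname accessors
#' @export
setGeneric("classCodes", function(x) standardGeneric("classCodes"))

#' @rdname accessors
#' @export
setGeneric("costValues", function(x) standardGeneric("costValues"))

#' @rdname accessors
#' @export
setGeneric("qualityValues", function(x) standardGeneric("qualityValues"))

#' @rdname accessors
#' @export
setGeneric("analysisPoints", function(x) standardGeneric("analysisPoints"))

#' @rdname accessors
#' @export
setGeneric("dispersalBudgets", function(x) standardGeneric("dispersalBudgets"))

#' @rdname accessors
#' @param scale a budget (AHACube) or window radius in metres (HMDCube).
#' @export
setGeneric("scaleValues", function(x, scale) standardGeneric("scaleValues"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setMethod("gridSpec", "LandcoverStack", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("gridSpec", "ResistanceSurface", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("gridSpec", "SpeciesQualityGrid", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("gridSpec", "AnalysisGrid", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("stackYears", "LandcoverStack", function(x) x@years)

#' @rdname accessors
#' @export
setMethod("landcoverLayer", "LandcoverStack", function(x, year) {
  if (is.character(year)) {
    idx <- match(year, x@years)
    if (is.na(idx)) stop("unknown time step: ", year)
  } else idx <- as.integer(year)
  x@layers[[idx]]
})

#' @rdname accessors
#' @export
setMethod("classCodes", "LandcoverStack", function(x) x@classCodes)

#' @rdname accessors
#' @export
setMethod("costValues", "ResistanceSurface", function(x) x@cost)

#' @rdname accessors
#' @export
setMethod("qualityValues", "SpeciesQualityGrid", function(x) x@quality)

#' @rdname accessors
#' @export
setMethod("analysisPoints", "AnalysisGrid", function(x) x@points)

.cube_budgets <- function(x) S4Vectors::metadata(x)$budgets

#' @rdname accessors
#' @export
setMethod("dispersalBudgets", "AHACube", .cube_budgets)

#' @rdname accessors
#' @export
setMethod("dispersalBudgets", "HMDCube", .cube_budgets)

.cube_scale <- function(x, scale) {
  nm <- as.character(scale)
  if (!nm %in% SummarizedExperiment::assayNames(x))
    stop("no scale '", nm, "'; available: ",
         paste(SummarizedExperiment::assayNames(x), collapse = ", "))
  SummarizedExperiment::assay(x, nm)
}

#' @rdname accessors
#' @export
setMethod("scaleValues", "AHACube", .cube_scale)

#' @rdname accessors
#' @export
setMethod("scaleValues", "HMDCube", .cube_scale)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m, origin (%g, %g), crs '%s'\n",
              object@nRows, object@nCols, object@cellSize,
              object@originX, object@originY, object@crs))
})

setMethod("show", "LandcoverStack", function(object) {
  cat(sprintf("LandcoverStack: %d time steps (%s)\n",
              length(object@years), paste(object@years, collapse = ", ")))
  show(object@grid)
  tab <- table(factor(object@layers[[length(object@layers)]],
                      levels = object@classCodes,
                      labels = names(object@classCodes)))
  cat("  latest layer composition:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "ResistanceSurface", function(object) {
  cat(sprintf("ResistanceSurface (%s): cost range [%g, %g] per pixel\n",
              object@year, min(object@cost), max(object@cost)))
  show(object@grid)
})

setMethod("show", "AnalysisGrid", function(object) {
  cat(sprintf("AnalysisGrid: %d focal points at %g m spacing\n",
              nrow(object@points), object@spacing))
})

setMethod("show", "SpeciesQualityGrid", function(object) {
  cat(sprintf("SpeciesQualityGrid: %d x %d cells of %g m, quality 0-9 (mean %.2f)\n",
              object@grid@nRows, object@grid@nCols, object@grid@cellSize,
              mean(object@quality)))
})

setMethod("show", "KernelResult", function(object) {
  cat(sprintf(
    "KernelResult: focal (%d, %d), budget %g (R = %g m), %d cells reached, a_p = %g m^2\n",
    object@focalRow, object@focalCol, object@budget, object@radiusM,
    sum(object@reached), object@aP))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel (%s): k = %d, WCSS = %.4g (best of %d inits, seed %d)\n",
              object@mode, object@k, object@wcss, object@nInit, object@seed))
  cat("  cluster sizes:", paste(tabulate(object@labels, object@k),
                                collapse = " "), "\n")
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: %d matched pairs, %d unmatched, %g points off-diagonal\n",
              nrow(object@mapping), length(object@unmatched), object@totalCost))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: %d clusters, %d permutations, %g%% confidence\n",
              nrow(object@summary), object@nPerm, 100 * object@confidence))
  print(object@summary, row.names = FALSE)
})
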