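#' @include AllClasses.R kernels.R
NULL

#' Human Modification Density baseline
#'
#' The fixed-shape moving-window baseline AHA is compared against: for each
#' focal point, time step and window radius, the percentage of cells within
#' a circular window (centred on the focal cell) that are road or building.
#' Window radii correspond to the dispersal distances used for AHA; windows
#' are clipped at the landscape edge and the denominator with them. Lakes
#' and open land contribute zero.
#'
#' @param stack a [LandcoverStack-class].
#' @param grid an [AnalysisGrid-class].
#' @param radii window radii in metres (defaults to the frictionless radii
#'   of the standard budgets).
#' @return an [HMDCube-class] (`SummarizedExperiment`; rows = focal points,
#'   columns = time steps, one assay per radius, values in percent).
#' @export
computeHMD <- function(stack, grid = buildAnalysisGrid(stack),
                       radii = c(250, 500, 1000, 2000, 4000)) {
  g <- stack@grid
  if (any(radii < g@cellSize))
    stop("configuration error: window radius smaller than one cell")
  radii <- sort(radii)
  pts <- grid@points
  years <- stack@years
  codes <- stack@classCodes
  radCells <- radii / g@cellSize
  assays <- lapply(radii, function(r)
    matrix(NA_real_, nrow(pts), length(years),
           dimnames = list(pts$point_id, years)))
  names(assays) <- as.character(radii)
  for (t in seq_along(years)) {
    v <- hmd_window_counts(stack@layers[[t]], pts$row, pts$col, radCells,
                           codes[["road"]], codes[["building"]])
    for (s in seq_along(radii)) assays[[s]][, t] <- v[, s]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(pts[, c("point_id", "x", "y", "row", "col")],
                                   row.names = pts$point_id),
    colData = S4Vectors::DataFrame(year = years, row.names = years),
    metadata = list(budgets = radii, radii_m = radii,
                    cellSize = g@cellSize, spacing = grid@spacing,
                    gridInfo = list(originX = g@originX, originY = g@originY,
                                    nRows = g@nRows, nCols = g@nCols,
                                    cellSize = g@cellSize, crs = g@crs))
  )
  new("HMDCube", se)
}
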