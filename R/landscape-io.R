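#' @include AllClasses.R asciiGrid.R
NULL

#' Read a land-cover time series from ASCII grid rasters
#'
#' Reads one coded raster per time step, checks that all layers share the
#' same geometry, and validates the class codes (unknown codes are rejected
#' with the offending cell named). `writeLandcoverStack` writes the stack
#' back, one `.asc` file per time step; a written stack reads back
#' bit-exactly.
#'
#' @param paths character vector of raster file paths, one per time step,
#'   in chronological order.
#' @param years time-step labels; defaults to `names(paths)`.
#' @param classCodes named integer vector mapping class names to codes
#'   (default `c(open = 0, road = 1, building = 2, lake = 3)`).
#' @param crs coordinate-reference-system identifier.
#' @return a [LandcoverStack-class].
#' @export
readLandcoverStack <- function(paths, years = names(paths),
                               classCodes = .LC_CODES, crs = "local") {
  if (is.null(years)) stop("time-step labels required (years or names(paths))")
  stopifnot(length(paths) == length(years))
  rasters <- lapply(paths, readAsciiGrid, crs = crs)
  g <- rasters[[1L]]$grid
  for (t in seq_along(rasters)[-1L]) {
    gt <- rasters[[t]]$grid
    if (gt@nRows != g@nRows || gt@nCols != g@nCols ||
        gt@cellSize != g@cellSize ||
        gt@originX != g@originX || gt@originY != g@originY)
      stop("alignment error: raster ", paths[t],
           " does not share the grid of ", paths[1L])
  }
  layers <- lapply(rasters, function(r) {
    if (anyNA(r$values)) stop("land-cover rasters must not contain nodata cells")
    m <- r$values
    storage.mode(m) <- "integer"
    m
  })
  LandcoverStack(grid = g, years = years, layers = layers,
                 classCodes = classCodes)
}

#' @param stack a [LandcoverStack-class].
#' @param dir output directory (created if absent).
#' @rdname readLandcoverStack
#' @export
writeLandcoverStack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("landcover_%s.asc", stack@years))
  for (t in seq_along(paths))
    writeAsciiGrid(stack@layers[[t]], stack@grid, paths[t])
  names(paths) <- stack@years
  invisible(paths)
}

#' Lay a regular lattice of focal points over a landscape
#'
#' Places one focal point per `spacing` x `spacing` block fully inside the
#' landscape extent, at the centre of the fine cell nearest the block
#' centroid (for blocks spanning an even number of cells the tie is broken
#' towards the lower-right cell). AHA and HMD are evaluated at these
#' points; the default 250 m spacing matches the analysis resolution the
#' smallest dispersal distance supports.
#'
#' @param stack a [LandcoverStack-class] (or a [GridSpec-class]).
#' @param spacing block edge length in metres; must be a positive multiple
#'   of the fine cell size.
#' @return an [AnalysisGrid-class].
#' @examples
#' g <- GridSpec(100, 100, cellSize = 10)
#' nrow(analysisPoints(buildAnalysisGrid(g, 250)))  # 16
#' @export
buildAnalysisGrid <- function(stack, spacing = 250) {
  g <- if (is(stack, "LandcoverStack")) stack@grid else stack
  stopifnot(is(g, "GridSpec"))
  b <- spacing / g@cellSize
  if (spacing <= 0 || abs(b - round(b)) > 1e-9)
    stop("configuration error: spacing (", spacing,
         " m) must be a positive multiple of the cell size (", g@cellSize, " m)")
  b <- as.integer(round(b))
  nbr <- g@nRows %/% b
  nbc <- g@nCols %/% b
  if (nbr < 1L || nbc < 1L)
    stop("landscape extent smaller than one ", spacing, " m block")
  blocks <- expand.grid(block_row = seq_len(nbr), block_col = seq_len(nbc),
                        KEEP.OUT.ATTRS = FALSE)
  ## centre cell of each block; even b ties towards the lower-right
  off <- b %/% 2L + 1L
  row <- (blocks$block_row - 1L) * b + off
  col <- (blocks$block_col - 1L) * b + off
  pts <- data.frame(
    point_id = sprintf("p%04d", seq_len(nrow(blocks))),
    x = g@originX + (col - 0.5) * g@cellSize,
    y = g@originY - (row - 0.5) * g@cellSize,
    row = row, col = col,
    block_row = blocks$block_row, block_col = blocks$block_col,
    stringsAsFactors = FALSE
  )
  new("AnalysisGrid", spacing = spacing, points = pts, grid = g)
}

#' Attach species-quality values to the analysis grid
#'
#' For every focal point, takes the maximum quality over the coarse
#' (typically 100 m) cells that intersect its analysis block with positive
#' area, and derives the presence flag (max quality >= 1) and the
#' high-quality flag (max quality >= 5). The maximum, rather than an
#' area-weighted mean, is used so that any presence signal within the block
#' is preserved.
#'
#' @param quality a [SpeciesQualityGrid-class].
#' @param grid an [AnalysisGrid-class].
#' @return data.frame with columns `point_id`, `x`, `y`, `quality`,
#'   `presence`, `high_quality`.
#' @export
alignQualityToGrid <- function(quality, grid) {
  qg <- quality@grid
  fg <- grid@grid
  sp <- grid@spacing
  pts <- grid@points
  qx0 <- qg@originX; qy0 <- qg@originY; qcs <- qg@cellSize
  qmax <- integer(nrow(pts))
  overlap_any <- FALSE
  for (i in seq_len(nrow(pts))) {
    bx0 <- fg@originX + (pts$block_col[i] - 1L) * sp
    bx1 <- bx0 + sp
    by0 <- fg@originY - (pts$block_row[i] - 1L) * sp
    by1 <- by0 - sp
    jmin <- max(1L, as.integer(floor((bx0 - qx0) / qcs + 1e-9)) + 1L)
    jmax <- min(qg@nCols, as.integer(ceiling((bx1 - qx0) / qcs - 1e-9)))
    imin <- max(1L, as.integer(floor((qy0 - by0) / qcs + 1e-9)) + 1L)
    imax <- min(qg@nRows, as.integer(ceiling((qy0 - by1) / qcs - 1e-9)))
    if (jmin > jmax || imin > imax) {
      qmax[i] <- NA_integer_
    } else {
      overlap_any <- TRUE
      qmax[i] <- max(quality@quality[imin:imax, jmin:jmax])
    }
  }
  if (!overlap_any)
    stop("extent error: species-quality raster does not overlap the analysis grid")
  data.frame(
    point_id = pts$point_id, x = pts$x, y = pts$y,
    quality = qmax,
    presence = !is.na(qmax) & qmax >= 1L,
    high_quality = !is.na(qmax) & qmax >= 5L,
    stringsAsFactors = FALSE
  )
}
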