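#' @include AllClasses.R resistance.R landscape-io.R
#' @useDynLib AHAscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Frictionless radius implied by a dispersal budget
#'
#' Under the configured base cost, a budget of `b` cost units carries a
#' disperser `b * cellSize / baseCostPerPixel` metres through frictionless
#' land; this radius R defines the normalizing disc area \eqn{\pi R^2} of
#' the AHA metric. With the default base cost of 10 per 10 m pixel, one
#' cost unit equals one metre, so the default budgets 250, 500, 1000, 2000
#' and 4000 correspond to the same dispersal distances in metres.
#'
#' @param budget dispersal budget(s) in cost units.
#' @param cellSize fine cell size in metres.
#' @param baseCostPerPixel cost of one permeable pixel crossing.
#' @return radius in metres.
#' @export
budgetRadius <- function(budget, cellSize = 10, baseCostPerPixel = 10) {
  stopifnot(all(budget > 0))
  budget * cellSize / baseCostPerPixel
}

#' Truncated cost-distance kernel around a focal cell
#'
#' Runs a Dijkstra shortest-path accumulation from the focal cell over the
#' 8-connected raster graph, with edge weight
#' `step_length / cellSize * (cost_src + cost_dst) / 2` (orthogonal steps of
#' one cell size, diagonal steps sqrt(2) times longer), truncated at the
#' dispersal budget (cells at exactly the budget are included). The focal
#' cell costs nothing to occupy, even on a barrier. The search is windowed
#' to a square of half-width equal to the frictionless radius around the
#' focal cell; this is lossless because no cell beyond that radius can be
#' reached within the budget.
#'
#' @param surface a [ResistanceSurface-class].
#' @param focalRow,focalCol fine-grid index of the focal cell.
#' @param budget dispersal budget in cost units.
#' @param baseCostPerPixel base cost used to derive the frictionless radius.
#' @param window logical; window the search (default) or run on the full
#'   grid (identical results, for verification).
#' @return a [KernelResult-class].
#' @examples
#' g <- GridSpec(21, 21, cellSize = 10)
#' surf <- new("ResistanceSurface", grid = g,
#'             cost = matrix(10, 21, 21), year = "t1")
#' costDistanceKernel(surf, 11, 11, budget = 50)
#' @export
costDistanceKernel <- function(surface, focalRow, focalCol, budget,
                               baseCostPerPixel = 10, window = TRUE) {
  g <- surface@grid
  if (focalRow < 1L || focalRow > g@nRows || focalCol < 1L ||
      focalCol > g@nCols)
    stop("domain error: focal cell outside the grid")
  if (budget <= 0) stop("domain error: budget must be positive")
  radiusM <- budgetRadius(budget, g@cellSize, baseCostPerPixel)
  if (window) {
    w <- as.integer(floor(budget / baseCostPerPixel))
    r0 <- max(1L, focalRow - w); r1 <- min(g@nRows, focalRow + w)
    c0 <- max(1L, focalCol - w); c1 <- min(g@nCols, focalCol + w)
  } else {
    r0 <- 1L; r1 <- g@nRows; c0 <- 1L; c1 <- g@nCols
  }
  sub <- surface@cost[r0:r1, c0:c1, drop = FALSE]
  acc <- dijkstra_accumulate(sub, focalRow - r0 + 1L, focalCol - c0 + 1L,
                             budget)
  reached <- acc <= budget
  new("KernelResult",
      focalRow = as.integer(focalRow), focalCol = as.integer(focalCol),
      budget = budget, radiusM = radiusM, acc = acc, reached = reached,
      rowOffset = as.integer(r0 - 1L), colOffset = as.integer(c0 - 1L),
      cellSize = g@cellSize,
      aP = sum(reached) * g@cellSize^2)
}

#' Amount of Habitat Available at the focal points of one time step
#'
#' For each focal point and dispersal budget, computes the truncated
#' cost-distance kernel and normalizes the reached area by the frictionless
#' disc: \eqn{AHA_p = a_p / (\pi R^2)}, making habitat availability
#' comparable across dispersal distances. One Dijkstra run at the largest
#' budget serves all budgets of a point, since the accumulated costs below
#' any smaller budget are identical.
#'
#' @param surface a [ResistanceSurface-class].
#' @param grid an [AnalysisGrid-class].
#' @param budgets numeric vector of dispersal budgets (cost units).
#' @param baseCostPerPixel base cost per permeable pixel.
#' @return numeric matrix, points x budgets (columns named by budget).
#' @export
computeAHA <- function(surface, grid, budgets = c(250, 500, 1000, 2000, 4000),
                       baseCostPerPixel = 10) {
  stopifnot(length(budgets) >= 1L, all(budgets > 0))
  budgets <- sort(budgets)
  g <- surface@grid
  pts <- grid@points
  radii <- budgetRadius(budgets, g@cellSize, baseCostPerPixel)
  discCells <- pi * (radii / g@cellSize)^2  # disc area in cell units
  out <- matrix(NA_real_, nrow(pts), length(budgets),
                dimnames = list(pts$point_id, as.character(budgets)))
  bmax <- budgets[length(budgets)]
  for (i in seq_len(nrow(pts))) {
    kr <- costDistanceKernel(surface, pts$row[i], pts$col[i], bmax,
                             baseCostPerPixel)
    for (s in seq_along(budgets))
      out[i, s] <- sum(kr@acc <= budgets[s]) / discCells[s]
  }
  out
}

#' Full AHA cube over time steps and dispersal budgets
#'
#' Builds the resistance surface of every time step and evaluates
#' [computeAHA()] on each, assembling an [AHACube-class]
#' (a `SummarizedExperiment`: rows = focal points, columns = time steps,
#' one assay per budget). Focal points are computed independently, so
#' results do not depend on evaluation order.
#'
#' @param stack a [LandcoverStack-class].
#' @param config a [resistanceConfig()] list.
#' @param grid an [AnalysisGrid-class]; defaults to a 250 m lattice.
#' @param budgets dispersal budgets in cost units.
#' @return an [AHACube-class].
#' @export
computeAHACube <- function(stack, config = resistanceConfig(),
                           grid = buildAnalysisGrid(stack),
                           budgets = c(250, 500, 1000, 2000, 4000)) {
  budgets <- sort(budgets)
  pts <- grid@points
  years <- stack@years
  assays <- lapply(budgets, function(b)
    matrix(NA_real_, nrow(pts), length(years),
           dimnames = list(pts$point_id, years)))
  names(assays) <- as.character(budgets)
  for (t in seq_along(years)) {
    surf <- buildResistanceSurface(stack, t, config)
    aha <- computeAHA(surf, grid, budgets, config$baseCostPerPixel)
    for (s in seq_along(budgets)) assays[[s]][, t] <- aha[, s]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(pts[, c("point_id", "x", "y", "row", "col")],
                                   row.names = pts$point_id),
    colData = S4Vectors::DataFrame(year = years, row.names = years),
    metadata = list(budgets = budgets,
                    radii_m = budgetRadius(budgets, stack@grid@cellSize,
                                           config$baseCostPerPixel),
                    baseCostPerPixel = config$baseCostPerPixel,
                    cellSize = stack@grid@cellSize,
                    spacing = grid@spacing,
                    gridInfo = list(originX = stack@grid@originX,
                                    originY = stack@grid@originY,
                                    nRows = stack@grid@nRows,
                                    nCols = stack@grid@nCols,
                                    cellSize = stack@grid@cellSize,
                                    crs = stack@grid@crs))
  )
  new("AHACube", se)
}

#' Convert a kernel's reached set to a polygon
#'
#' Traces the boundary of the union of reached cell squares into closed
#' rings (outer boundaries counter-clockwise, holes clockwise in map
#' coordinates), so the signed shoelace area of all rings equals the
#' reached area `a_p` exactly.
#'
#' @param kernel a [KernelResult-class] with a non-empty reached set.
#' @param grid the [GridSpec-class] of the surface the kernel was computed
#'   on (for map coordinates); defaults to window-local coordinates with
#'   origin (0, nRows * cellSize).
#' @return list with elements `rings` (list of closed two-column x/y
#'   matrices) and `area` (signed shoelace total, equal to `a_p`).
#' @export
kernelToPolygon <- function(kernel, grid = NULL) {
  reached <- kernel@reached
  if (!any(reached)) stop("empty reached set")
  nr <- nrow(reached); nc <- ncol(reached)
  cs <- kernel@cellSize
  if (is.null(grid)) {
    ## window-local map coordinates: full-grid top-left at (0, 0), y up
    ox <- kernel@colOffset * cs
    oy0 <- -(kernel@rowOffset * cs)
  } else {
    ox <- grid@originX + kernel@colOffset * cs
    oy0 <- grid@originY - kernel@rowOffset * cs
  }
  ## Directed boundary edges with the interior on the left (map coords, y up).
  ## Corner (vr, vc), vr in 0..nr, vc in 0..nc: x = ox + vc*cs, y = oy0 - vr*cs.
  inset <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && reached[r, c]
  from <- integer(0); to <- integer(0)
  key <- function(vr, vc) vr * (nc + 1L) + vc
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!reached[r, c]) next
    if (!inset(r + 1L, c)) { from <- c(from, key(r, c - 1L)); to <- c(to, key(r, c)) }        # bottom BL->BR
    if (!inset(r, c + 1L)) { from <- c(from, key(r, c));      to <- c(to, key(r - 1L, c)) }   # right BR->TR
    if (!inset(r - 1L, c)) { from <- c(from, key(r - 1L, c)); to <- c(to, key(r - 1L, c - 1L)) } # top TR->TL
    if (!inset(r, c - 1L)) { from <- c(from, key(r - 1L, c - 1L)); to <- c(to, key(r, c - 1L)) } # left TL->BL
  }
  ## Chain directed edges into closed rings (Eulerian decomposition).
  ord <- order(from)
  from_s <- from[ord]; to_s <- to[ord]
  first <- match(unique(from_s), from_s)
  names(first) <- unique(from_s)
  used <- logical(length(from_s))
  nexts <- function(v) {
    i <- first[as.character(v)]
    if (is.na(i)) return(NA_integer_)
    while (i <= length(from_s) && from_s[i] == v) {
      if (!used[i]) return(i)
      i <- i + 1L
    }
    NA_integer_
  }
  rings <- list()
  area <- 0
  for (start in seq_along(from_s)) {
    if (used[start]) next
    verts <- from_s[start]
    i <- start
    repeat {
      used[i] <- TRUE
      v <- to_s[i]
      verts <- c(verts, v)
      if (v == verts[1L]) break
      i <- nexts(v)
      if (is.na(i)) stop("internal error: open ring in polygon trace")
    }
    vr <- verts %/% (nc + 1L); vc <- verts %% (nc + 1L)
    xy <- cbind(x = ox + vc * cs, y = oy0 - vr * cs)
    n <- nrow(xy)
    a <- 0.5 * sum(xy[-n, 1L] * xy[-1L, 2L] - xy[-1L, 1L] * xy[-n, 2L])
    area <- area + a
    rings[[length(rings) + 1L]] <- xy
  }
  list(rings = rings, area = area)
}

#' Long-format table of a cube
#'
#' Flattens an [AHACube-class] or [HMDCube-class] into the long CSV schema
#' (`point_id`, `x`, `y`, `year`, `scale`, `metric`, `value`).
#'
#' @param cube an `AHACube` or `HMDCube`.
#' @return data.frame in long format.
#' @export
cubeToLong <- function(cube) {
  rd <- as.data.frame(SummarizedExperiment::rowData(cube))
  years <- colnames(cube)
  metric <- if (is(cube, "AHACube")) "aha" else "hmd"
  out <- do.call(rbind, lapply(SummarizedExperiment::assayNames(cube),
    function(a) {
      v <- SummarizedExperiment::assay(cube, a)
      data.frame(point_id = rep(rd$point_id, times = length(years)),
                 x = rep(rd$x, times = length(years)),
                 y = rep(rd$y, times = length(years)),
                 year = rep(years, each = nrow(v)),
                 scale = as.numeric(a), metric = metric,
                 value = as.vector(v), stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}
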