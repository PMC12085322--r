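#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text single-band raster I/O in the ESRI ASCII grid (.asc) format:
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, optional `NODATA_value`) followed by the cell values, top row
#' first. Values equal to the nodata sentinel are returned as `NA`.
#' The CRS, which the format cannot carry, is supplied or recorded through
#' the `crs` argument.
#'
#' @param path file path.
#' @param crs coordinate-reference-system identifier to attach on read.
#' @return `readAsciiGrid` returns a list with elements `grid`
#'   (a [GridSpec-class]) and `values` (a numeric matrix, row 1 = top row).
#' @examples
#' f <- tempfile(fileext = ".asc")
#' writeAsciiGrid(matrix(0:3, 2, 2), GridSpec(2, 2, cellSize = 10), f)
#' readAsciiGrid(f)$values
#' @export
readAsciiGrid <- function(path, crs = "local") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated ASCII grid header in ", path)
    parts <- strsplit(trimws(line), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2L])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("incomplete ASCII grid header in ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(con, what = numeric(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cell values in ", path, ", got ", length(vals))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  grid <- GridSpec(nRows = nr, nCols = nc, cellSize = hdr$cellsize,
                   originX = hdr$xllcorner,
                   originY = hdr$yllcorner + nr * hdr$cellsize, crs = crs)
  list(grid = grid, values = m)
}

#' @param values numeric or integer matrix, row 1 = top row.
#' @param grid a [GridSpec-class] describing the geometry.
#' @param nodata sentinel written for `NA` cells.
#' @rdname readAsciiGrid
#' @export
writeAsciiGrid <- function(values, grid, path, nodata = -9999) {
  stopifnot(is.matrix(values),
            nrow(values) == grid@nRows, ncol(values) == grid@nCols)
  vals <- values
  vals[is.na(vals)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid@nCols),
    sprintf("nrows %d", grid@nRows),
    sprintf("xllcorner %.10g", grid@originX),
    sprintf("yllcorner %.10g", grid@originY - grid@nRows * grid@cellSize),
    sprintf("cellsize %.10g", grid@cellSize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(vals, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
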