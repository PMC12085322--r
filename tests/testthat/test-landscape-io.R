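test_that("ASCII grid rasters round-trip bit-exactly", {
  g <- GridSpec(12, 9, cellSize = 10, originX = 300, originY = 840)
  m <- matrix(sample(0:3, 12 * 9, replace = TRUE), 12, 9)
  f <- tempfile(fileext = ".asc")
  writeAsciiGrid(m, g, f)
  r <- readAsciiGrid(f)
  expect_equal(r$values, m, ignore_attr = TRUE)
  expect_equal(r$grid@originX, g@originX)
  expect_equal(r$grid@originY, g@originY)
  expect_equal(r$grid@cellSize, g@cellSize)

  ## NA cells survive through the nodata sentinel
  m2 <- matrix(runif(20), 4, 5)
  m2[2, 3] <- NA
  f2 <- tempfile(fileext = ".asc")
  writeAsciiGrid(m2, GridSpec(4, 5, cellSize = 2.5), f2)
  expect_equal(readAsciiGrid(f2)$values, m2, ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("land-cover stacks validate geometry and class codes", {
  g <- GridSpec(10, 10, cellSize = 10)
  d <- tempfile(); dir.create(d)
  l1 <- matrix(0L, 10, 10); l1[3, 3] <- 1L
  l2 <- l1; l2[5, 5] <- 2L
  writeAsciiGrid(l1, g, file.path(d, "a.asc"))
  writeAsciiGrid(l2, g, file.path(d, "b.asc"))
  st <- readLandcoverStack(file.path(d, c("a.asc", "b.asc")),
                           years = c("1899", "2012"))
  expect_s4_class(st, "LandcoverStack")
  expect_length(stackYears(st), 2L)

  ## stack written then read reproduces codes bit-exactly
  d2 <- tempfile()
  paths <- writeLandcoverStack(st, d2)
  st2 <- readLandcoverStack(paths, names(paths))
  expect_identical(unname(st2@layers), unname(st@layers))

  ## differing cell size -> alignment error
  writeAsciiGrid(l1, GridSpec(10, 10, cellSize = 20), file.path(d, "c.asc"))
  expect_error(readLandcoverStack(file.path(d, c("a.asc", "c.asc")),
                                  years = c("t1", "t2")), "alignment")

  ## unknown class code rejected, naming the cell
  bad <- l1; bad[4, 7] <- 7L
  writeAsciiGrid(bad, g, file.path(d, "bad.asc"))
  expect_error(readLandcoverStack(file.path(d, "bad.asc"), years = "t1"),
               "unknown class code 7.*row 4, col 7")
})

test_that("lake mask must be identical across time steps", {
  g <- GridSpec(5, 5, cellSize = 10)
  l1 <- matrix(0L, 5, 5); l1[1, 1] <- 3L
  l2 <- matrix(0L, 5, 5); l2[2, 2] <- 3L
  expect_error(LandcoverStack(g, c("t1", "t2"), list(l1, l2)), "lake mask")
  expect_s4_class(LandcoverStack(g, c("t1", "t2"), list(l1, l1)),
                  "LandcoverStack")
})

test_that("analysis grid lays one focal point per full block", {
  g <- GridSpec(100, 100, cellSize = 10)
  ag <- buildAnalysisGrid(g, 250)
  pts <- analysisPoints(ag)
  expect_equal(nrow(pts), 16L)  # floor(1000/250)^2
  ## points on a regular 250 m lattice at fine-cell centres
  expect_true(all(diff(sort(unique(pts$x))) == 250))
  expect_true(all(pts$row >= 1 & pts$row <= 100))

  ## spacing equal to the full extent -> a single central point
  ag1 <- buildAnalysisGrid(g, 1000)
  expect_equal(nrow(analysisPoints(ag1)), 1L)
  expect_equal(analysisPoints(ag1)$row, 51L)

  ## spacing not a multiple of the cell size -> configuration error
  expect_error(buildAnalysisGrid(g, 255), "configuration error")
})

test_that("quality aggregation takes the block maximum and flags thresholds", {
  fineG <- GridSpec(50, 50, cellSize = 10)   # 500 m x 500 m, 2x2 blocks
  ag <- buildAnalysisGrid(fineG, 250)
  ## coarse 100 m grid, 5x5
  q <- matrix(0L, 5, 5)
  ## block (1,1) covers coarse cells rows 1..3, cols 1..3
  q[1, 2] <- 3L          # quality 3 in block (1,1): presence, not high
  q[4, 5] <- 5L          # high quality in block (2,2)
  qg <- SpeciesQualityGrid(GridSpec(5, 5, cellSize = 100), q)
  tab <- alignQualityToGrid(qg, ag)
  expect_equal(nrow(tab), 4L)
  b11 <- tab[tab$x == min(tab$x) & tab$y == max(tab$y), ]
  expect_equal(b11$quality, 3L)
  expect_true(b11$presence); expect_false(b11$high_quality)
  b22 <- tab[tab$x == max(tab$x) & tab$y == min(tab$y), ]
  expect_equal(b22$quality, 5L)
  expect_true(b22$high_quality)

  ## all-zero quality -> presence false everywhere
  tab0 <- alignQualityToGrid(
    SpeciesQualityGrid(GridSpec(5, 5, cellSize = 100), matrix(0L, 5, 5)), ag)
  expect_false(any(tab0$presence))

  ## presence count equals brute-force block maxima on random fields
  set.seed(31)
  for (rep in 1:5) {
    qr <- matrix(sample(0:9, 25, replace = TRUE, prob = c(8, rep(1, 9))),
                 5, 5)
    tabr <- alignQualityToGrid(
      SpeciesQualityGrid(GridSpec(5, 5, cellSize = 100), qr), ag)
    brute <- sapply(seq_len(4), function(i) {
      br <- analysisPoints(ag)$block_row[i]; bc <- analysisPoints(ag)$block_col[i]
      rows <- max(1, (br - 1) * 2.5 %/% 1 + 1):min(5, ceiling(br * 2.5))
      cols <- max(1, (bc - 1) * 2.5 %/% 1 + 1):min(5, ceiling(bc * 2.5))
      max(qr[rows, cols])
    })
    expect_equal(tabr$quality, as.integer(brute))
    expect_equal(sum(tabr$presence), sum(brute >= 1))
  }

  ## no overlap -> extent error
  far <- SpeciesQualityGrid(
    GridSpec(5, 5, cellSize = 100, originX = 10000, originY = 10000),
    matrix(1L, 5, 5))
  expect_error(alignQualityToGrid(far, ag), "extent error")
})
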