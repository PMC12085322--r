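test_that("a near-zero budget reaches only the focal cell", {
  surf <- uniformSurface(11)
  k <- costDistanceKernel(surf, 6, 6, budget = 1e-4)
  expect_equal(sum(k@reached), 1L)
  expect_equal(k@aP, 100)
  expect_error(costDistanceKernel(surf, 0, 6, 100), "domain error")
  expect_error(costDistanceKernel(surf, 6, 6, -5), "domain error")
})

test_that("accumulated costs equal the independent relaxation oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    cost <- matrix(10, n, n)
    ## sprinkle barriers of the three classes
    nb <- sample(0:round(n * n / 4), 1)
    cost[sample(n * n, nb)] <- sample(c(98.76543, 250, 500), nb,
                                      replace = TRUE)
    fr <- sample(n, 1); fc <- sample(n, 1)
    budget <- runif(1, 50, 600)
    oracle <- bellmanFordAcc(cost, fr, fc)
    k <- costDistanceKernel(surfaceFrom(cost), fr, fc, budget,
                            window = FALSE)
    inb <- oracle <= budget
    expect_identical(k@reached, inb)
    expect_equal(k@acc[inb], oracle[inb], tolerance = 1e-12)
  }
})

test_that("a one-pixel building wall blocks budget 400 but not 600", {
  cost <- matrix(10, 41, 41)
  cost[, 21] <- 500                      # vertical wall
  surf <- surfaceFrom(cost)
  ## focal adjacent to the wall: two half-steps cost 255 + 255 = 510
  k400 <- costDistanceKernel(surf, 21, 20, budget = 400)
  maxCol <- function(k) max(which(k@reached, arr.ind = TRUE)[, 2]) +
    k@colOffset
  expect_equal(maxCol(k400), 21L)        # enters the wall, never beyond
  k600 <- costDistanceKernel(surf, 21, 20, budget = 600)
  expect_gt(maxCol(k600), 21L)           # crosses with 90 units to spare
  ## hand arithmetic of the two-step crossing
  acrossCost <- k600@acc[21, 22 - k600@colOffset]
  expect_equal(acrossCost, 510)
})

test_that("reached area is monotone in budget and under barrier addition", {
  set.seed(21)
  cost <- matrix(10, 25, 25)
  cost[sample(625, 60)] <- 250
  surf <- surfaceFrom(cost)
  budgets <- c(50, 100, 150, 220)
  areas <- sapply(budgets, function(b)
    costDistanceKernel(surf, 13, 13, b)@aP)
  expect_true(all(diff(areas) >= 0))

  ## adding barrier cells never increases the reached area
  cost2 <- cost
  cost2[sample(which(cost == 10), 40)] <- 500
  for (b in budgets) {
    a1 <- costDistanceKernel(surf, 13, 13, b)@aP
    a2 <- costDistanceKernel(surfaceFrom(cost2), 13, 13, b)@aP
    expect_lte(a2, a1)
  }
})

test_that("kernels are invariant under rotation and mirroring", {
  set.seed(5)
  cost <- matrix(10, 21, 21)
  cost[sample(441, 80)] <- sample(c(250, 500), 80, replace = TRUE)
  a0 <- costDistanceKernel(surfaceFrom(cost), 11, 11, 300)@aP
  rot <- t(cost[nrow(cost):1, ])                 # 90 degree rotation
  expect_equal(costDistanceKernel(surfaceFrom(rot), 11, 11, 300)@aP, a0)
  mir <- cost[, ncol(cost):1]
  expect_equal(costDistanceKernel(surfaceFrom(mir), 11, 11, 300)@aP, a0)
})

test_that("windowing is lossless", {
  set.seed(9)
  cost <- matrix(10, 61, 61)
  cost[sample(61 * 61, 300)] <- 250
  surf <- surfaceFrom(cost)
  kw <- costDistanceKernel(surf, 31, 31, 250, window = TRUE)
  kf <- costDistanceKernel(surf, 31, 31, 250, window = FALSE)
  expect_equal(kw@aP, kf@aP)
  ## the windowed reached set, placed back in full-grid coordinates,
  ## matches the unwindowed one
  full <- matrix(FALSE, 61, 61)
  full[kw@rowOffset + seq_len(nrow(kw@reached)),
       kw@colOffset + seq_len(ncol(kw@reached))] <- kw@reached
  expect_identical(full, kf@reached)
})

test_that("frictionless AHA approaches the octagonal-metric bound", {
  surf <- uniformSurface(121)
  ag <- buildAnalysisGrid(surf@grid, 1210)   # single central point
  aha <- computeAHA(surf, ag, budgets = c(250, 500))
  expect_true(all(aha >= 0.85 & aha <= 1.005))
  expect_equal(as.vector(aha[1, "250"]), 2 * sqrt(2) / pi, tolerance = 0.02)
})

test_that("a fully enclosed focal point keeps only its own cell", {
  cost <- matrix(10, 51, 51)
  cost[25:27, 25:27] <- 500
  cost[26, 26] <- 10
  surf <- surfaceFrom(cost)
  ag <- new("AnalysisGrid", spacing = 250, grid = surf@grid,
            points = data.frame(point_id = "p1", x = 255, y = 255,
                                row = 26L, col = 26L, block_row = 1L,
                                block_col = 1L))
  aha <- computeAHA(surf, ag, budgets = 250)
  expect_equal(as.vector(aha), 100 / (pi * 250^2), tolerance = 1e-9)
})

test_that("the AHA cube honours its shape, determinism and monotonicity contracts", {
  set.seed(77)
  g <- GridSpec(50, 50, cellSize = 10)
  l1 <- matrix(0L, 50, 50); l1[sample(2500, 80)] <- 1L
  l2 <- l1; l2[sample(which(l1 == 0L), 60)] <- 2L
  st <- LandcoverStack(g, c("t1", "t2"), list(l1, l2))
  ag <- buildAnalysisGrid(st, 250)
  cube <- computeAHACube(st, resistanceConfig(), ag, budgets = c(250, 500))
  expect_s4_class(cube, "AHACube")
  expect_equal(dim(cube), c(4L, 2L))
  expect_setequal(SummarizedExperiment::assayNames(cube), c("250", "500"))

  ## strictly more building cells -> elementwise no larger
  for (b in c("250", "500")) {
    v <- scaleValues(cube, b)
    expect_true(all(v[, "t2"] <= v[, "t1"]))
  }

  ## identical layers at two time steps -> identical slices
  st2 <- LandcoverStack(g, c("a", "b"), list(l1, l1))
  cube2 <- computeAHACube(st2, resistanceConfig(), ag, budgets = 250)
  v2 <- scaleValues(cube2, 250)
  expect_identical(v2[, "a"], v2[, "b"])
})

test_that("kernel polygons enclose exactly the reached area", {
  surf <- uniformSurface(15)
  ## single cell
  k1 <- costDistanceKernel(surf, 8, 8, budget = 1e-4)
  p1 <- kernelToPolygon(k1)
  expect_equal(p1$area, 100)
  expect_length(p1$rings, 1L)

  ## hand-built reached sets: 2x2 block and an L-shape
  mk <- function(mask) {
    new("KernelResult", focalRow = 1L, focalCol = 1L, budget = 1,
        radiusM = 1, acc = matrix(0, nrow(mask), ncol(mask)),
        reached = mask, rowOffset = 0L, colOffset = 0L, cellSize = 10,
        aP = sum(mask) * 100)
  }
  sq <- matrix(FALSE, 4, 4); sq[2:3, 2:3] <- TRUE
  expect_equal(kernelToPolygon(mk(sq))$area, 400)
  ell <- matrix(FALSE, 5, 5); ell[2:4, 2] <- TRUE; ell[4, 3:4] <- TRUE
  expect_equal(kernelToPolygon(mk(ell))$area, 100 * sum(ell))

  ## ring with a hole: outer ring CCW-positive, hole negative, sum exact
  ring <- matrix(TRUE, 5, 5); ring[3, 3] <- FALSE
  pr <- kernelToPolygon(mk(ring))
  expect_equal(pr$area, 2400)
  expect_length(pr$rings, 2L)

  ## a realistic kernel's polygon area equals a_p
  set.seed(3)
  cost <- matrix(10, 31, 31); cost[sample(961, 150)] <- 500
  k <- costDistanceKernel(surfaceFrom(cost), 16, 16, 200)
  expect_equal(kernelToPolygon(k)$area, k@aP)
})
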