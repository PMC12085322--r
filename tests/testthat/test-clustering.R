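test_that("K-Means separates planted trajectory groups perfectly", {
  centers <- rbind(c(0.9, 0.9, 0.8, 0.8), c(0.5, 0.4, 0.2, 0.1),
                   c(0.1, 0.1, 0.1, 0.1))
  x <- separableTrajectories(30, centers, sd = 0.01)
  m <- fitTsKmeans(x, 3, nInit = 5, seed = 2)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(clusterLabels(m),
                                         attr(x, "groups")), 1)
})

test_that("closed-form WCSS at the degenerate cluster counts", {
  x <- separableTrajectories(10, rbind(c(1, 0), c(0, 1)), sd = 0.05)
  m1 <- fitTsKmeans(x, 1, nInit = 3, seed = 1)
  expect_equal(m1@centroids[1, ], colMeans(x), ignore_attr = TRUE)
  expect_equal(m1@wcss, sum(sweep(x, 2, colMeans(x))^2))

  xs <- unique(round(x, 3))
  mk <- fitTsKmeans(xs, nrow(xs), nInit = 2, seed = 1)
  expect_equal(mk@wcss, 0)
  expect_error(fitTsKmeans(xs, nrow(xs) + 1, nInit = 2, seed = 1),
               "domain error")
})

test_that("clustering is deterministic given the seed and best-of-inits", {
  x <- separableTrajectories(20, rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                             sd = 0.2)
  m1 <- fitTsKmeans(x, 3, nInit = 8, seed = 42)
  m2 <- fitTsKmeans(x, 3, nInit = 8, seed = 42)
  expect_identical(clusterLabels(m1), clusterLabels(m2))
  expect_identical(m1@centroids, m2@centroids)
  ## returned wcss is no worse than any initialization tried
  expect_true(all(m1@wcss <= m1@initWcss + 1e-9))
  expect_error(fitTsKmeans(x, 3, nInit = 8), "seed")
})

test_that("spatial clustering works on a single time step of a cube", {
  fx <- cachedFixture("tiny")
  m <- fitSpatialKmeans(fx$cube, "2012", k = 2, nInit = 5, seed = 3)
  expect_s4_class(m, "ClusterModel")
  expect_equal(m@mode, "spatial")
  expect_equal(ncol(m@centroids), 2L)  # one feature per budget
  m2 <- fitSpatialKmeans(fx$cube, "2012", k = 2, nInit = 5, seed = 3)
  expect_identical(clusterLabels(m), clusterLabels(m2))
  ## the two bands of the tiny fixture separate on the final year alone
  pts <- analysisPoints(fx$grid)
  band <- ifelse(pts$row <= 75, 1L, 2L)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(clusterLabels(m), band), 0.9)
})

test_that("WCSS curves are non-increasing and scale with duplication", {
  x <- separableTrajectories(15, rbind(c(1, 0), c(0, 1), c(1, 1)), sd = 0.1)
  curve <- wcssCurve(x, 1:6, nInit = 10, seed = 9)
  expect_true(all(diff(curve$wcss) <= 1e-8))
  ## duplicating every row doubles the WCSS (k below the planted count,
  ## where the optimum is unambiguous)
  x2 <- rbind(x, x)
  curve2 <- wcssCurve(x2, 1:4, nInit = 20, seed = 9)
  curveR <- wcssCurve(x, 1:4, nInit = 20, seed = 9)
  expect_equal(curve2$wcss, 2 * curveR$wcss, tolerance = 1e-6)
  ## k_range of a single k
  c1 <- wcssCurve(x, 1, nInit = 2, seed = 9)
  expect_equal(c1$wcss, sum(sweep(x, 2, colMeans(x))^2))
})

test_that("elbow selection finds planted structure and flags flat declines", {
  centers <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  x <- separableTrajectories(40, centers, sd = 0.02)
  curve <- wcssCurve(x, 1:7, nInit = 10, seed = 4)
  expect_equal(selectKElbow(curve), 3L)
  expect_equal(selectKElbow(curve, override = 5), 5L)

  lin <- data.frame(k = 1:6, wcss = seq(100, 0, length.out = 6))
  expect_warning(kk <- selectKElbow(lin), "no elbow")
  expect_equal(kk, 2L)
  expect_error(selectKElbow(data.frame(k = 1:2, wcss = c(2, 1))),
               "domain error")
})

test_that("label alignment is optimal, handles permutations and rectangles", {
  a <- rep(1:4, each = 10)
  ## identical labelings: identity mapping at zero cost
  al0 <- alignClusterLabels(a, a)
  expect_equal(al0@totalCost, 0)
  expect_equal(al0@mapping$a, al0@mapping$b)

  ## a pure relabeling is recovered exactly
  perm <- c(3, 1, 4, 2)
  al1 <- alignClusterLabels(a, perm[a])
  expect_equal(al1@totalCost, 0)
  expect_equal(perm[as.integer(al1@mapping$a)],
               as.integer(al1@mapping$b))

  ## rectangular case: surplus clusters reported unmatched
  b <- a; b[a == 4] <- 3
  al2 <- alignClusterLabels(a, b)
  expect_length(al2@unmatched, 1L)
  expect_equal(nrow(al2@mapping), 3L)

  ## confusion table margins add up
  expect_equal(rowSums(al2@confusion), as.numeric(table(a)),
               ignore_attr = TRUE)
  expect_equal(sum(al2@confusion), length(a))
  expect_error(alignClusterLabels(a, a[-1]), "domain error")
})

test_that("alignment matches brute-force enumeration on random labelings", {
  set.seed(13)
  for (rep in 1:30) {
    kA <- sample(2:5, 1); kB <- sample(2:6, 1)
    n <- 60
    la <- sample(kA, n, replace = TRUE)
    lb <- sample(kB, n, replace = TRUE)
    ## ensure every label occurs
    la[seq_len(kA)] <- seq_len(kA); lb[seq_len(kB)] <- seq_len(kB)
    al <- alignClusterLabels(la, lb)
    expect_equal(al@totalCost, bruteAlignCost(al@confusion, n))
    expect_equal(nrow(al@mapping), min(kA, kB))
  }
})

test_that("labels are equivariant under row permutation of the data", {
  x <- separableTrajectories(20, rbind(c(1, 0), c(0, 1), c(0.5, 1.5)),
                             sd = 0.05)
  m <- fitTsKmeans(x, 3, nInit = 6, seed = 8)
  set.seed(123); p <- sample(nrow(x))
  mp <- fitTsKmeans(x[p, ], 3, nInit = 6, seed = 8)
  ## same partition up to label names: zero misalignment
  expect_equal(alignClusterLabels(clusterLabels(m)[p],
                                  clusterLabels(mp))@totalCost, 0)
})
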