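#' @include AllClasses.R kernels.R
NULL

#' Flatten an AHA cube into a trajectory feature matrix
#'
#' Multi-dimensional time-series K-Means under the Euclidean metric is
#' exactly K-Means on the flattened (time step x budget) vector, so the
#' trajectory features of each focal point are its T x S AHA values laid
#' out budget-major (all years of the first budget, then the next budget).
#' No feature scaling is applied: AHA is already normalized to be
#' comparable across dispersal distances.
#'
#' @param cube an [AHACube-class].
#' @return numeric matrix points x (T*S) with attributes `featureYears` and
#'   `featureBudgets` describing each column.
#' @export
trajectoryMatrix <- function(cube) {
  budgets <- dispersalBudgets(cube)
  years <- colnames(cube)
  m <- do.call(cbind, lapply(as.character(budgets), function(b)
    SummarizedExperiment::assay(cube, b)))
  colnames(m) <- paste0("b", rep(budgets, each = length(years)), "_",
                        rep(years, times = length(budgets)))
  attr(m, "featureYears") <- rep(years, times = length(budgets))
  attr(m, "featureBudgets") <- rep(budgets, each = length(years))
  m
}

## Best-of-nInit Lloyd/Hartigan-Wong K-Means with seeded distinct-row
## initial centres, so every initialization's WCSS is retained and the run
## is deterministic given the seed.
.bestKmeans <- function(x, k, nInit, seed) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values in the feature matrix")
  ux <- unique(x)
  if (k > nrow(ux))
    stop("domain error: k (", k, ") exceeds the number of distinct rows (",
         nrow(ux), ")")
  if (k == nrow(ux)) {
    ## every distinct row is its own centroid; WCSS is exactly zero
    key <- function(m) apply(format(m, digits = 17), 1L, paste,
                             collapse = "\r")
    lab <- match(key(x), key(ux))
    km <- list(centers = ux, cluster = lab, tot.withinss = 0)
    return(list(km = km, initWcss = rep(0, nInit)))
  }
  best <- NULL
  initW <- numeric(nInit)
  for (i in seq_len(nInit)) {
    set.seed(seed + i - 1L)
    centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
    km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = 100L))
    initW[i] <- km$tot.withinss
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(km = best, initWcss = initW)
}

#' K-Means clustering of AHA trajectories
#'
#' `fitTsKmeans` clusters focal points by their full (time step x budget)
#' AHA trajectory; `fitSpatialKmeans` clusters the values of a single time
#' step across budgets (the contemporary-data comparison). Both run
#' best-of-`nInit` K-Means under the Euclidean metric with seeded
#' initializations, so results are reproducible bit-for-bit given the seed.
#'
#' @param x a trajectory matrix from [trajectoryMatrix()], or an
#'   [AHACube-class] (flattened internally).
#' @param k number of clusters; must not exceed the number of distinct rows.
#' @param nInit number of random initializations (default 10).
#' @param seed integer seed (mandatory for reproducibility).
#' @return a [ClusterModel-class].
#' @export
fitTsKmeans <- function(x, k, nInit = 10L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is(x, "AHACube")) x <- trajectoryMatrix(x)
  fy <- attr(x, "featureYears"); fb <- attr(x, "featureBudgets")
  fit <- .bestKmeans(x, k, nInit, seed)
  new("ClusterModel", k = as.integer(k), centroids = fit$km$centers,
      labels = as.integer(fit$km$cluster), wcss = fit$km$tot.withinss,
      initWcss = fit$initWcss, seed = as.integer(seed),
      nInit = as.integer(nInit), mode = "timeseries",
      featureYears = if (is.null(fy)) character() else fy,
      featureBudgets = if (is.null(fb)) numeric() else fb)
}

#' @param cube an [AHACube-class].
#' @param year the single time step (label or index) to cluster on.
#' @rdname fitTsKmeans
#' @export
fitSpatialKmeans <- function(cube, year, k, nInit = 10L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  budgets <- dispersalBudgets(cube)
  if (!is.character(year)) year <- colnames(cube)[as.integer(year)]
  if (!year %in% colnames(cube)) stop("unknown time step: ", year)
  m <- vapply(as.character(budgets), function(b)
    SummarizedExperiment::assay(cube, b)[, year], numeric(nrow(cube)))
  colnames(m) <- paste0("b", budgets)
  fit <- .bestKmeans(m, k, nInit, seed)
  new("ClusterModel", k = as.integer(k), centroids = fit$km$centers,
      labels = as.integer(fit$km$cluster), wcss = fit$km$tot.withinss,
      initWcss = fit$initWcss, seed = as.integer(seed),
      nInit = as.integer(nInit), mode = "spatial",
      featureYears = rep(year, length(budgets)),
      featureBudgets = as.numeric(budgets))
}

#' Within-cluster sum of squares across a range of k
#'
#' Fits best-of-`nInit` K-Means for each k and records the best WCSS; the
#' curve is non-increasing in k up to optimization noise and feeds the
#' elbow selection.
#'
#' @param x feature matrix (or [AHACube-class], flattened).
#' @param kRange ascending integer vector of cluster counts.
#' @param nInit,seed as in [fitTsKmeans()].
#' @return data.frame with columns `k` and `wcss`.
#' @export
wcssCurve <- function(x, kRange = 1:10, nInit = 10L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is(x, "AHACube")) x <- trajectoryMatrix(x)
  if (is.unsorted(kRange)) stop("kRange must be ascending")
  wcss <- vapply(kRange, function(k)
    .bestKmeans(x, k, nInit, seed)$km$tot.withinss, numeric(1))
  data.frame(k = as.integer(kRange), wcss = wcss)
}

#' Elbow selection of the cluster count
#'
#' Picks the k with the largest discrete second difference (curvature) of
#' the WCSS curve — the point where adding clusters stops paying. The
#' published analyses selected k by visual inspection of the same curve, so
#' a manual `override` is supported; a flat (linear) decline carries no
#' elbow and falls back to the smallest interior k with a warning.
#'
#' @param curve data.frame from [wcssCurve()] (at least 3 rows).
#' @param override optional manually chosen k, returned as-is.
#' @return selected k (integer).
#' @export
selectKElbow <- function(curve, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  if (nrow(curve) < 3L)
    stop("domain error: need at least 3 points on the WCSS curve")
  w <- curve$wcss
  n <- length(w)
  d2 <- w[seq_len(n - 2L)] - 2 * w[seq(2L, n - 1L)] + w[seq(3L, n)]
  scale <- max(abs(w[1L] - w[n]), .Machine$double.eps)
  if (max(d2) <= 1e-6 * scale) {
    warning("no elbow: WCSS declines linearly; returning the smallest interior k")
    return(curve$k[2L])
  }
  curve$k[which.max(d2) + 1L]
}

## O(n^3) shortest-augmenting-path Hungarian algorithm on a square cost
## matrix; returns the column assigned to each row. Ported from the classic
## potentials formulation (no solver package for the linear assignment
## problem is available to build on).
.hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)        # row potentials, index i+1 (i = 0 virtual)
  v <- numeric(n + 1L)        # col potentials, index j+1 (j = 0 virtual)
  p <- integer(n + 1L)        # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Optimal assignment between two cluster labelings
#'
#' Aligns two labelings of the same point set with the Kuhn-Munkres
#' (Hungarian) algorithm, maximizing the number of points on the mapped
#' diagonal of the confusion table (equivalently minimizing the
#' misalignment). When the labelings have different cluster counts, the
#' surplus clusters of the larger side are left unmatched and reported.
#'
#' @param labelsA,labelsB vectors of cluster labels over the same points.
#' @return an [AlignmentResult-class].
#' @examples
#' a <- rep(1:3, each = 4)
#' alignClusterLabels(a, c(3, 1, 2)[a])@totalCost  # 0: pure relabeling
#' @export
alignClusterLabels <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop("domain error: labelings must cover the same points")
  la <- sort(unique(labelsA)); lb <- sort(unique(labelsB))
  conf <- unclass(as.matrix(table(factor(labelsA, levels = la),
                                  factor(labelsB, levels = lb))))
  conf <- matrix(as.numeric(conf), nrow(conf), ncol(conf))
  dimnames(conf) <- list(A = as.character(la), B = as.character(lb))
  kA <- length(la); kB <- length(lb)
  K <- max(kA, kB)
  cmax <- max(conf)
  ## real-real pairings cost 2*(cmax - overlap); pairings with a padding
  ## dummy cost 2*cmax + 1, so maximal overlap is primary and real pairs
  ## are preferred on ties -> exactly min(kA, kB) matched pairs.
  cost <- matrix(2 * cmax + 1, K, K)
  cost[seq_len(kA), seq_len(kB)] <- 2 * (cmax - conf)
  assign <- .hungarian(cost)
  pairs <- data.frame(a = character(0), b = character(0),
                      overlap = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(kA)) {
    j <- assign[i]
    if (j <= kB)
      pairs <- rbind(pairs, data.frame(
        a = as.character(la[i]), b = as.character(lb[j]),
        overlap = conf[i, j], stringsAsFactors = FALSE))
  }
  unmatched <- if (kA > kB) {
    setdiff(as.character(la), pairs$a)
  } else if (kB > kA) {
    setdiff(as.character(lb), pairs$b)
  } else character(0)
  new("AlignmentResult", mapping = pairs, unmatched = unmatched,
      confusion = conf, totalCost = length(labelsA) - sum(pairs$overlap))
}
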