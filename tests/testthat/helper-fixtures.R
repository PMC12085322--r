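## Shared fixtures and independent oracles for the test suite. Everything
## is generated in code; heavyweight cubes are memoised per session.

.fixture_cache <- new.env(parent = emptyenv())

cachedFixture <- function(name, seed = 1L) {
  key <- paste0(name, "_", seed)
  if (!exists(key, envir = .fixture_cache)) {
    fx <- fixtureScenario(name, seed)
    stack <- generateLandscapeSeries(fx$spec)
    grid <- buildAnalysisGrid(stack, fx$spacing)
    cube <- computeAHACube(stack, resistanceConfig(), grid, fx$budgets)
    assign(key, list(fx = fx, stack = stack, grid = grid, cube = cube),
           envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

uniformSurface <- function(n, cost = 10, cellSize = 10) {
  new("ResistanceSurface", grid = GridSpec(n, n, cellSize = cellSize),
      cost = matrix(cost, n, n), year = "t1")
}

surfaceFrom <- function(cost, cellSize = 10) {
  new("ResistanceSurface",
      grid = GridSpec(nrow(cost), ncol(cost), cellSize = cellSize),
      cost = cost, year = "t1")
}

## Independent shortest-path oracle: vectorized Bellman-Ford relaxation
## over the 8-connected raster graph with the arithmetic-mean edge rule.
## Deliberately shares no code with the package's Dijkstra.
bellmanFordAcc <- function(cost, focalRow, focalCol) {
  nr <- nrow(cost); nc <- ncol(cost)
  d <- matrix(Inf, nr, nc)
  d[focalRow, focalCol] <- 0
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  repeat {
    d0 <- d
    for (s in seq_len(nrow(shifts))) {
      dr <- shifts$dr[s]; dc <- shifts$dc[s]
      len <- if (dr != 0 && dc != 0) sqrt(2) else 1
      ## candidate distance arriving at (i, j) from (i - dr, j - dc)
      ri <- seq_len(nr); rj <- seq_len(nc)
      ti <- ri[ri - dr >= 1 & ri - dr <= nr]
      tj <- rj[rj - dc >= 1 & rj - dc <= nc]
      w <- len * (cost[ti, tj, drop = FALSE] +
                    cost[ti - dr, tj - dc, drop = FALSE]) / 2
      cand <- d[ti - dr, tj - dc, drop = FALSE] + w
      d[ti, tj] <- pmin(d[ti, tj, drop = FALSE], cand)
    }
    if (identical(d, d0)) break
  }
  d
}

## Brute-force per-window road/building percentage (HMD oracle)
bruteHmd <- function(layer, focalRow, focalCol, radiusCells) {
  nr <- nrow(layer); nc <- ncol(layer)
  hit <- 0L; tot <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if ((i - focalRow)^2 + (j - focalCol)^2 <= radiusCells^2) {
      tot <- tot + 1L
      if (layer[i, j] %in% c(1L, 2L)) hit <- hit + 1L
    }
  }
  100 * hit / tot
}

## Brute-force minimal misalignment over all assignments (k <= 6)
bruteAlignCost <- function(conf, n) {
  kA <- nrow(conf); kB <- ncol(conf)
  if (kA <= kB) {
    perms <- .permutations(kB)
    best <- Inf
    for (p in seq_len(nrow(perms))) {
      ov <- sum(conf[cbind(seq_len(kA), perms[p, seq_len(kA)])])
      best <- min(best, n - ov)
    }
  } else {
    perms <- .permutations(kA)
    best <- Inf
    for (p in seq_len(nrow(perms))) {
      ov <- sum(conf[cbind(perms[p, seq_len(kB)], seq_len(kB))])
      best <- min(best, n - ov)
    }
  }
  best
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n))[-i][sub], nrow(sub), n - 1L))
  }))
}

## Well-separated Gaussian trajectory groups for clustering tests
separableTrajectories <- function(nPerGroup = 30L, centers, sd = 0.01,
                                  seed = 5L) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g) {
    matrix(rep(centers[g, ], each = nPerGroup), nPerGroup) +
      matrix(rnorm(nPerGroup * ncol(centers), sd = sd), nPerGroup)
  }))
  attr(x, "groups") <- rep(seq_len(nrow(centers)), each = nPerGroup)
  x
}
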