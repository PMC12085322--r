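#' @include synth.R validation.R clustering.R
NULL

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML (or equivalent list) with a mandatory
#' `seed`, either a `fixture` name or a `landcover` block
#' (`years`, `paths`) plus a `species` raster path, and optional
#' `spacing`, `budgets`, `resistance`, `clustering` and `validation`
#' blocks. Missing optional blocks take the replication defaults.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed))
    stop("validation error: config must declare a seed")
  if (is.null(config$fixture) &&
      (is.null(config$landcover) || is.null(config$species)))
    stop("validation error: config needs either a fixture name or landcover + species inputs")
  config$spacing <- config$spacing %||% 250
  config$budgets <- unlist(config$budgets %||% c(250, 500, 1000, 2000, 4000))
  rc <- config$resistance %||% list()
  config$resistanceConfig <- resistanceConfig(
    ranks = unlist(rc$ranks %||% c(lake = 2, road = 2.5, building = 3)),
    rankMax = rc$rankMax %||% 3, contrast = rc$contrast %||% 4,
    cmaxPerPixel = rc$cmax %||% 500, baseCostPerPixel = rc$base %||% 10,
    overrides = unlist(rc$overrides %||% c(road = 250, building = 500)))
  cl <- config$clustering %||% list()
  config$clustering <- list(kRange = unlist(cl$kRange %||% c(1L, 8L)),
                            k = cl$k, nInit = cl$nInit %||% 10L)
  va <- config$validation %||% list()
  config$validation <- list(
    nPerm = va$nPerm %||% 1000L, confidence = va$confidence %||% 0.99,
    fraction = va$fraction %||% 0.3, balance = va$balance %||% 0.5,
    reps = va$reps %||% 25L, degree = va$degree %||% 1L)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full habitat-availability pipeline
#'
#' Sequences the module operations end to end: inputs (fixture generation
#' or raster reading), resistance surfaces, AHA cube, HMD cube, trajectory
#' and spatial clustering with elbow selection, label alignment, the
#' permutation overlap test, and the GLM battery. All tabular stage
#' outputs are written as CSV, rasters as ASCII grids, and a
#' machine-readable JSON manifest (inputs, seeds, output checksums) closes
#' the run; reruns with an identical config produce identical checksums.
#'
#' @param config config list or YAML path (see [readPipelineConfig()]).
#' @param outdir output directory (overrides `config$outdir`).
#' @return (invisibly) the manifest list.
#' @export
runPipeline <- function(config, outdir = NULL) {
  cfg <- readPipelineConfig(config)
  outdir <- outdir %||% cfg$outdir %||% stop("outdir required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  outputs <- character()
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  ## --- inputs ---------------------------------------------------------
  if (!is.null(cfg$fixture)) {
    note("stage inputs: generating fixture '%s' (seed %d)", cfg$fixture,
         cfg$seed)
    fx <- stage("inputs", fixtureScenario(cfg$fixture, cfg$seed))
    stack <- stage("inputs", generateLandscapeSeries(fx$spec))
    cfg$budgets <- fx$budgets
    cfg$spacing <- fx$spacing
    grid <- buildAnalysisGrid(stack, cfg$spacing)
    cube0 <- computeAHACube(stack, cfg$resistanceConfig, grid, cfg$budgets)
    quality <- stage("inputs", generateSpeciesQuality(cube0, fx$spec))
    inputsDesc <- list(fixture = cfg$fixture)
  } else {
    note("stage inputs: reading %d land-cover rasters",
         length(cfg$landcover$paths))
    stack <- stage("inputs", readLandcoverStack(
      unlist(cfg$landcover$paths), as.character(unlist(cfg$landcover$years))))
    q <- stage("inputs", readAsciiGrid(cfg$species))
    quality <- SpeciesQualityGrid(q$grid, q$values)
    grid <- buildAnalysisGrid(stack, cfg$spacing)
    cube0 <- NULL
    inputsDesc <- list(landcover = unlist(cfg$landcover$paths),
                       species = cfg$species)
  }

  ## --- resistance -----------------------------------------------------
  note("stage resistance: %d time steps", length(stack@years))
  surfaces <- stage("resistance", buildResistanceSeries(stack,
                                                        cfg$resistanceConfig))
  for (y in names(surfaces)) {
    p <- file.path(outdir, sprintf("resistance_%s.asc", y))
    writeAsciiGrid(surfaces[[y]]@cost, surfaces[[y]]@grid, p)
    outputs <- c(outputs, p)
  }

  ## --- AHA cube -------------------------------------------------------
  note("stage aha: %d points x %d budgets", nrow(grid@points),
       length(cfg$budgets))
  cube <- if (!is.null(cube0)) cube0 else
    stage("aha", computeAHACube(stack, cfg$resistanceConfig, grid,
                                cfg$budgets))
  p <- file.path(outdir, "aha_long.csv")
  utils::write.csv(cubeToLong(cube), p, row.names = FALSE)
  outputs <- c(outputs, p)

  ## --- HMD cube -------------------------------------------------------
  note("stage hmd")
  radii <- budgetRadius(cfg$budgets, stack@grid@cellSize,
                        cfg$resistanceConfig$baseCostPerPixel)
  hmd <- stage("hmd", computeHMD(stack, grid, radii))
  p <- file.path(outdir, "hmd_long.csv")
  utils::write.csv(cubeToLong(hmd), p, row.names = FALSE)
  outputs <- c(outputs, p)

  ## --- clustering -----------------------------------------------------
  tm <- trajectoryMatrix(cube)
  kr <- cfg$clustering$kRange
  kRange <- seq(kr[1L], kr[length(kr)])
  note("stage clustering: k range %d..%d", min(kRange), max(kRange))
  curve <- stage("clustering", wcssCurve(tm, kRange, cfg$clustering$nInit,
                                         seed = cfg$seed))
  k <- stage("clustering", selectKElbow(curve, override = cfg$clustering$k))
  tsModel <- stage("clustering", fitTsKmeans(tm, k, cfg$clustering$nInit,
                                             seed = cfg$seed))
  spModel <- stage("clustering", fitSpatialKmeans(
    cube, ncol(cube), k, cfg$clustering$nInit, seed = cfg$seed + 1L))
  p <- file.path(outdir, "wcss_curve.csv")
  utils::write.csv(curve, p, row.names = FALSE)
  outputs <- c(outputs, p)
  p <- file.path(outdir, "clusters.csv")
  utils::write.csv(data.frame(point_id = rownames(cube),
                              cluster_ts = tsModel@labels,
                              cluster_spatial = spModel@labels),
                   p, row.names = FALSE)
  outputs <- c(outputs, p)

  ## --- alignment ------------------------------------------------------
  note("stage alignment")
  al <- stage("alignment", alignClusterLabels(tsModel@labels,
                                              spModel@labels))
  p <- file.path(outdir, "alignment.csv")
  utils::write.csv(al@mapping, p, row.names = FALSE)
  outputs <- c(outputs, p)
  p <- file.path(outdir, "confusion.csv")
  utils::write.csv(as.data.frame(al@confusion), p, row.names = FALSE)
  outputs <- c(outputs, p)

  ## --- species & permutation test -------------------------------------
  note("stage permutation: %d shuffles", cfg$validation$nPerm)
  presence <- stage("permutation", alignQualityToGrid(quality, grid))
  perm <- stage("permutation", permutationOverlapTest(
    tsModel@labels, presence$presence, cfg$validation$nPerm,
    cfg$validation$confidence, seed = cfg$seed + 2L))
  p <- file.path(outdir, "presence.csv")
  utils::write.csv(presence, p, row.names = FALSE)
  outputs <- c(outputs, p)
  p <- file.path(outdir, "permutation.csv")
  utils::write.csv(perm@summary, p, row.names = FALSE)
  outputs <- c(outputs, p)

  ## --- GLM battery ----------------------------------------------------
  note("stage glm: %d replicates per model", cfg$validation$reps)
  battery <- stage("glm", runGlmBattery(
    list(aha = cube, hmd = hmd), presence,
    degree = cfg$validation$degree, fraction = cfg$validation$fraction,
    balance = cfg$validation$balance, reps = cfg$validation$reps,
    seed = cfg$seed + 3L))
  p <- file.path(outdir, "glm_battery.csv")
  utils::write.csv(battery, p, row.names = FALSE)
  outputs <- c(outputs, p)

  manifest <- list(
    package = "AHAscape",
    version = as.character(utils::packageVersion("AHAscape")),
    seed = cfg$seed,
    inputs = inputsDesc,
    parameters = list(spacing = cfg$spacing, budgets = cfg$budgets,
                      k = k, nPerm = cfg$validation$nPerm,
                      reps = cfg$validation$reps),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))),
    log = log
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log, file.path(outdir, "run.log"))
  invisible(manifest)
}
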