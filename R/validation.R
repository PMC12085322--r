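#' @include AllClasses.R clustering.R
NULL

#' Permutation test of cluster-presence overlap
#'
#' Shuffles cluster labels `nPerm` times, preserving the number of points
#' per cluster, and records the species-presence count falling in each
#' cluster under every shuffle. A cluster significantly *overlaps*
#' presence if its observed count is greater than the null count in at
#' least `confidence` of the permutations, and significantly *deters* if it
#' is less than the null in at least `confidence` of them (strict
#' inequalities against the empirical null).
#'
#' @param labels cluster labels per focal point.
#' @param presence logical presence flag per focal point.
#' @param nPerm number of permutations (default 1000, minimum 100).
#' @param confidence confidence level (default 0.99).
#' @param seed integer seed.
#' @return a [PermutationResult-class].
#' @export
permutationOverlapTest <- function(labels, presence, nPerm = 1000L,
                                   confidence = 0.99, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(labels) != length(presence))
    stop("labels and presence must be aligned per point")
  if (nPerm < 100L) stop("nPerm must be at least 100")
  presence <- as.logical(presence)
  lev <- sort(unique(labels))
  k <- length(lev)
  li <- match(labels, lev)
  n <- length(labels)
  npres <- sum(presence)
  observed <- tabulate(li[presence], nbins = k)
  set.seed(seed)
  null <- matrix(0L, k, nPerm)
  if (npres > 0L) {
    for (b in seq_len(nPerm)) {
      idx <- sample.int(n, npres)
      null[, b] <- tabulate(li[idx], nbins = k)
    }
  }
  fracGreater <- rowMeans(observed > null)
  fracLess <- rowMeans(observed < null)
  verdict <- rep("not_significant", k)
  verdict[fracGreater >= confidence] <- "overlaps"
  verdict[fracLess >= confidence] <- "deters"
  summ <- data.frame(
    cluster = as.character(lev), size = tabulate(li, nbins = k),
    observed = observed, null_mean = rowMeans(null),
    frac_greater = fracGreater, frac_less = fracLess,
    verdict = verdict, stringsAsFactors = FALSE
  )
  new("PermutationResult", summary = summ, null = null,
      nPerm = as.integer(nPerm), confidence = confidence,
      seed = as.integer(seed))
}

#' Stratified presence/absence subsample
#'
#' Draws, without replacement, `floor(fraction * n)` rows with a fixed
#' presence share `balance` (default 50/50), the device used to thin
#' spatially autocorrelated data while balancing the classes despite a low
#' presence rate.
#'
#' @param table data.frame with a logical `presence` column.
#' @param fraction fraction of rows to keep (default 0.3).
#' @param balance presence share of the subsample (default 0.5).
#' @param seed integer seed.
#' @return row-subset of `table`.
#' @export
stratifiedSubsample <- function(table, fraction = 0.3, balance = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(fraction > 0, fraction <= 1, balance > 0, balance < 1)
  pres <- which(table$presence)
  abs_ <- which(!table$presence)
  total <- floor(fraction * nrow(table))
  nPres <- round(total * balance)
  nAbs <- total - nPres
  if (length(pres) < nPres)
    stop("insufficient presence rows: need ", nPres, ", have ", length(pres))
  if (length(abs_) < nAbs)
    stop("insufficient absence rows: need ", nAbs, ", have ", length(abs_))
  set.seed(seed)
  idx <- c(sample(pres, nPres), sample(abs_, nAbs))
  table[sort(idx), , drop = FALSE]
}

#' Binomial GLM of presence on habitat metrics
#'
#' Logistic regression (IRLS via `stats::glm`) of presence/absence on one
#' or more habitat predictors, standardized to zero mean and unit SD within
#' the supplied data so that slopes are per-SD. `degree = 2` adds squared
#' terms of the standardized predictors. Perfect separation is flagged
#' (`separation = TRUE`) so callers can exclude the replicate.
#'
#' @param data data.frame with a logical `presence` column and the
#'   predictor columns.
#' @param predictors character vector of predictor column names.
#' @param degree 1 (linear) or 2 (adds squared terms).
#' @return list of class `ahaGlmFit`: `model` (the glm), `coefficients`,
#'   `predictors`, `degree`, `fitted`, `presence`, `separation`,
#'   `center`/`scale` used for standardization.
#' @export
fitBinomialGlm <- function(data, predictors, degree = 1L) {
  stopifnot(degree %in% c(1L, 2L), all(predictors %in% names(data)))
  z <- as.matrix(data[, predictors, drop = FALSE])
  ctr <- colMeans(z)
  scl <- apply(z, 2L, stats::sd)
  if (any(scl == 0))
    stop("constant predictor: ", paste(predictors[scl == 0], collapse = ", "))
  z <- sweep(sweep(z, 2L, ctr), 2L, scl, "/")
  df <- as.data.frame(z)
  names(df) <- predictors
  form <- paste("presence ~", paste(predictors, collapse = " + "))
  if (degree == 2L)
    form <- paste(form, "+",
                  paste(sprintf("I(%s^2)", predictors), collapse = " + "))
  df$presence <- as.logical(data$presence)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::as.formula(form), family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) separation <- TRUE
  structure(list(model = fit, coefficients = stats::coef(fit),
                 predictors = predictors, degree = degree,
                 fitted = stats::fitted(fit), presence = df$presence,
                 separation = separation, center = ctr, scale = scl),
            class = "ahaGlmFit")
}

#' Rank-based ROC-AUC
#'
#' Mann-Whitney form of the area under the ROC curve of a score against a
#' binary truth, with ties counted half. Invariant to strictly monotone
#' transforms of the score.
#'
#' @param score numeric predictions (e.g. fitted probabilities), or an
#'   `ahaGlmFit` whose fitted values are evaluated in-sample.
#' @param truth logical presence vector (ignored for an `ahaGlmFit`).
#' @return AUC in \[0, 1\].
#' @export
computeAuc <- function(score, truth) {
  if (inherits(score, "ahaGlmFit")) {
    truth <- score$presence
    score <- score$fitted
  }
  truth <- as.logical(truth)
  nPos <- sum(truth)
  nNeg <- sum(!truth)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC undefined: evaluation set holds a single class")
  r <- rank(score)
  (sum(r[truth]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Probability-scale effect size of standardized slopes
#'
#' The inverse logit of a standardized GLM slope: the probability-like
#' association per standard deviation of the predictor, equal to 0.5 for no
#' effect, above 0.5 for positive association, below for negative, and
#' strictly increasing in the slope. (The published analyses report an
#' effect size with exactly this centering and sign behaviour without
#' giving a formula; the inverse logit is the simplest transform with those
#' properties and is the package's documented operationalization.)
#'
#' @param fit an `ahaGlmFit`, or a numeric vector of slopes.
#' @return named vector of effect sizes, one per (linear) predictor.
#' @examples
#' effectSize(0)  # 0.5
#' @export
effectSize <- function(fit) {
  if (inherits(fit, "ahaGlmFit")) {
    beta <- fit$coefficients[fit$predictors]
  } else {
    beta <- fit
  }
  stats::plogis(beta)
}

## Predictor table for one metric cube, year and scale ("Allscales" = all).
.predictorTable <- function(cube, year, scale) {
  budgets <- as.character(dispersalBudgets(cube))
  scales <- if (identical(scale, "Allscales")) budgets else as.character(scale)
  m <- vapply(scales, function(b)
    SummarizedExperiment::assay(cube, b)[, year], numeric(nrow(cube)))
  colnames(m) <- paste0("s", scales)
  as.data.frame(m)
}

#' GLM battery over metrics, years and dispersal scales
#'
#' For each metric cube supplied, each time step, and each dispersal scale
#' plus the combined "Allscales" model, fits `reps` seeded
#' subsample-fit-evaluate replicates: a stratified 50/50 subsample of
#' `fraction` of the points, a binomial GLM of presence on the
#' standardized predictor(s), the in-sample rank AUC, and the
#' probability-scale effect size. Replicate r of every battery cell uses
#' subsampling seed `seed + r - 1`, so the AHA and HMD batteries see the
#' same subsamples and are directly comparable. Replicates with perfect
#' separation are excluded from the aggregates with a warning.
#'
#' @param cubes named list of cubes, e.g.
#'   `list(aha = <AHACube>, hmd = <HMDCube>)`.
#' @param presence logical vector aligned to the cube rows (or the
#'   data.frame from [alignQualityToGrid()], matched by `point_id`).
#' @param degree 1 or 2 (adds squared terms).
#' @param fraction,balance,reps subsampling scheme (defaults 0.3, 0.5, 25).
#' @param seed master seed for the replicate counter scheme.
#' @param includeFull also fit each model once on the full data without
#'   subsampling (`scale` rows flagged `subsampled = FALSE`).
#' @return data.frame with one row per metric x year x scale (columns
#'   `metric`, `year`, `scale`, `degree`, `auc_mean`, `auc_min`, `auc_max`,
#'   `effect_mean`, `n_reps_used`, `subsampled`) and a `replicates`
#'   attribute holding the per-replicate records.
#' @export
runGlmBattery <- function(cubes, presence, degree = 1L, fraction = 0.3,
                          balance = 0.5, reps = 25L, seed,
                          includeFull = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  if (!is.list(cubes) || is.null(names(cubes)))
    stop("cubes must be a named list of AHACube/HMDCube objects")
  rows <- list(); repRows <- list()
  for (metric in names(cubes)) {
    cube <- cubes[[metric]]
    pres <- if (is.data.frame(presence)) {
      presence$presence[match(rownames(cube), presence$point_id)]
    } else as.logical(presence)
    if (length(pres) != nrow(cube) || anyNA(pres))
      stop("presence not aligned with cube rows for metric ", metric)
    scales <- c(as.character(dispersalBudgets(cube)), "Allscales")
    for (year in colnames(cube)) {
      for (scale in scales) {
        predTab <- .predictorTable(cube, year, scale)
        predTab$presence <- pres
        aucs <- numeric(0); effs <- numeric(0); used <- 0L
        for (r in seq_len(reps)) {
          sub <- stratifiedSubsample(predTab, fraction, balance,
                                     seed = seed + r - 1L)
          fit <- tryCatch(
            fitBinomialGlm(sub, setdiff(names(sub), "presence"), degree),
            error = function(e) NULL)
          if (is.null(fit)) next
          if (fit$separation) {
            warning(sprintf(
              "perfect separation in %s %s %s replicate %d; excluded",
              metric, year, scale, r))
            next
          }
          used <- used + 1L
          auc <- computeAuc(fit)
          eff <- mean(effectSize(fit))
          aucs <- c(aucs, auc); effs <- c(effs, eff)
          repRows[[length(repRows) + 1L]] <- data.frame(
            metric = metric, year = year, scale = scale, degree = degree,
            rep = r, auc = auc, effect = eff, stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, year = year, scale = scale, degree = degree,
          auc_mean = if (used) mean(aucs) else NA_real_,
          auc_min = if (used) min(aucs) else NA_real_,
          auc_max = if (used) max(aucs) else NA_real_,
          effect_mean = if (used) mean(effs) else NA_real_,
          n_reps_used = used, subsampled = TRUE, stringsAsFactors = FALSE)
        if (includeFull) {
          fit <- tryCatch(
            fitBinomialGlm(predTab, setdiff(names(predTab), "presence"),
                           degree),
            error = function(e) NULL)
          full_auc <- if (!is.null(fit) && !fit$separation)
            computeAuc(fit) else NA_real_
          full_eff <- if (!is.null(fit) && !fit$separation)
            mean(effectSize(fit)) else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            metric = metric, year = year, scale = scale, degree = degree,
            auc_mean = full_auc, auc_min = full_auc, auc_max = full_auc,
            effect_mean = full_eff, n_reps_used = 1L, subsampled = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- do.call(rbind, repRows)
  out
}
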