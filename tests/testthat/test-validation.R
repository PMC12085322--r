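test_that("permutation test flags constructed enrichment and nothing else", {
  set.seed(6)
  labels <- rep(1:4, each = 50)
  ## presence identical to membership of cluster 2
  presence <- labels == 2
  pr <- permutationOverlapTest(labels, presence, nPerm = 500, seed = 10)
  expect_equal(pr@summary$verdict[pr@summary$cluster == "2"], "overlaps")
  expect_true(all(pr@summary$verdict[pr@summary$cluster != "2"] == "deters"))
  expect_equal(sum(pr@summary$observed), sum(presence))
  expect_equal(dim(pr@null), c(4L, 500L))

  ## zero presences: everything not significant
  pr0 <- permutationOverlapTest(labels, rep(FALSE, 200), nPerm = 200,
                                seed = 1)
  expect_true(all(pr0@summary$verdict == "not_significant"))

  ## determinism
  prA <- permutationOverlapTest(labels, presence, nPerm = 200, seed = 3)
  prB <- permutationOverlapTest(labels, presence, nPerm = 200, seed = 3)
  expect_identical(prA@null, prB@null)
  expect_error(permutationOverlapTest(labels, presence, nPerm = 50,
                                      seed = 1), "at least 100")
  expect_error(permutationOverlapTest(labels, presence[-1], seed = 1),
               "aligned")
})

test_that("stratified subsampling yields the requested balanced draw", {
  set.seed(2)
  tab <- data.frame(id = 1:1000, presence = rep(c(TRUE, FALSE),
                                                c(200, 800)))
  sub <- stratifiedSubsample(tab, fraction = 0.3, balance = 0.5, seed = 4)
  expect_equal(nrow(sub), 300L)
  expect_equal(sum(sub$presence), 150L)
  expect_equal(sum(!sub$presence), 150L)
  expect_false(any(duplicated(sub$id)))

  sub2 <- stratifiedSubsample(tab, fraction = 0.3, balance = 0.5, seed = 4)
  expect_identical(sub, sub2)

  allPres <- data.frame(presence = rep(TRUE, 50))
  expect_error(stratifiedSubsample(allPres, 0.5, 0.5, seed = 1),
               "insufficient absence")
  few <- data.frame(presence = rep(c(TRUE, FALSE), c(5, 995)))
  expect_error(stratifiedSubsample(few, 0.3, 0.5, seed = 1),
               "insufficient presence.*need 150, have 5")
})

test_that("the binomial GLM recovers planted slopes on standardized predictors", {
  set.seed(14)
  n <- 10000
  z <- rnorm(n)
  ## beta = 0 generator: fitted slope ~ 0 within Monte-Carlo error
  d0 <- data.frame(p1 = z, presence = runif(n) < 0.4)
  f0 <- fitBinomialGlm(d0, "p1")
  expect_lt(abs(f0$coefficients[["p1"]]), 3 * summary(f0$model)$coefficients["p1", 2])

  ## planted slope 1 recovered within its standard error envelope
  d1 <- data.frame(p1 = z, presence = runif(n) < plogis(-0.5 + z))
  f1 <- fitBinomialGlm(d1, "p1")
  se <- summary(f1$model)$coefficients["p1", 2]
  expect_lt(abs(f1$coefficients[["p1"]] - 1), 4 * se)

  ## five predictors -> exactly five slope coefficients ("Allscales")
  d5 <- data.frame(matrix(rnorm(n * 5), n))
  names(d5) <- paste0("s", 1:5)
  d5$presence <- runif(n) < plogis(rowSums(d5) / 3)
  f5 <- fitBinomialGlm(d5, paste0("s", 1:5))
  expect_length(f5$coefficients[f5$predictors], 5L)

  ## squared terms added at degree 2
  f2 <- fitBinomialGlm(d1, "p1", degree = 2L)
  expect_true("I(p1^2)" %in% names(f2$coefficients))

  expect_error(fitBinomialGlm(data.frame(p1 = rep(1, 10),
                                         presence = rep(c(TRUE, FALSE), 5)),
                              "p1"), "constant predictor")

  ## perfect separation flagged
  ds <- data.frame(p1 = c(1:5, 11:15),
                   presence = rep(c(FALSE, TRUE), each = 5))
  expect_true(fitBinomialGlm(ds, "p1")$separation)
})

test_that("rank AUC behaves like a proper concordance measure", {
  set.seed(8)
  truth <- rep(c(TRUE, FALSE), each = 300)
  noise <- runif(600)
  expect_equal(computeAuc(noise, truth), 0.5, tolerance = 0.08)

  perfect <- ifelse(truth, 2, 1) + runif(600, 0, 0.5)
  expect_equal(computeAuc(perfect, truth), 1.0)
  expect_equal(computeAuc(1 - perfect, truth), 0.0)

  ## ties counted half: half of each class shares one score
  s <- c(1, 2, 2, 3); tr <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(computeAuc(s, tr), 0.875)  # (1 + 0.5 + 1 + 1)/4

  ## invariant under strictly monotone transforms
  sc <- rnorm(600) + truth
  expect_equal(computeAuc(sc, truth), computeAuc(plogis(3 * sc - 1), truth))

  skip_if_not_installed("pROC")
  expect_equal(computeAuc(sc, truth),
               as.numeric(pROC::auc(pROC::roc(truth, sc, quiet = TRUE))))

  expect_error(computeAuc(runif(5), rep(TRUE, 5)), "single class")
})

test_that("effect size is the inverse logit of the standardized slope", {
  expect_identical(effectSize(0), 0.5)
  b <- seq(-3, 3, by = 0.5)
  es <- effectSize(b)
  expect_true(all(diff(es) > 0))            # strictly increasing
  expect_true(all(es[b > 0] > 0.5) && all(es[b < 0] < 0.5))
  expect_equal(effectSize(50), 1, tolerance = 1e-9)  # saturates
})

test_that("the GLM battery has the contracted shape and reproducibility", {
  fx <- cachedFixture("tiny")
  quality <- generateSpeciesQuality(fx$cube, fx$fx$spec)
  pres <- alignQualityToGrid(quality, fx$grid)
  bat <- suppressWarnings(
    runGlmBattery(list(aha = fx$cube), pres, reps = 5, seed = 21))
  ## 2 years x (2 budgets + Allscales) for one metric
  expect_equal(nrow(bat), 6L)
  expect_setequal(unique(bat$scale), c("250", "500", "Allscales"))
  expect_true(all(bat$auc_mean >= 0 & bat$auc_mean <= 1, na.rm = TRUE))
  expect_true(all(bat$auc_min <= bat$auc_mean & bat$auc_mean <= bat$auc_max,
                  na.rm = TRUE))
  bat2 <- suppressWarnings(
    runGlmBattery(list(aha = fx$cube), pres, reps = 5, seed = 21))
  expect_identical(bat, bat2)   # bit-for-bit given the seed vector
})
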