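test_that("Dice coefficient handles identity, disjoint and empty sets", {
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  # |A| = 3, |B| = 4, |A intersect B| = 2 -> 4/7
  b <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(dice(a, b), 4 / 7)
  expect_equal(dice(logical(5), logical(5)), 1)
  # symmetry and bounds on random masks
  set.seed(2)
  for (i in 1:10) {
    x <- runif(50) > 0.5; y <- runif(50) > 0.3
    expect_identical(dice(x, y), dice(y, x))
    expect_gte(dice(x, y), 0); expect_lte(dice(x, y), 1)
  }
  # index-set form
  expect_equal(dice(1:3, 2:5), 4 / 7)
})

test_that("mean percent difference follows its definition", {
  expect_equal(meanPercentDifference(5, 5), 0)
  expect_equal(meanPercentDifference(1, 0.5), -50)
  expect_equal(meanPercentDifference(13.649, 16.949), 24.17760,
               tolerance = 1e-6)
  expect_warning(out <- meanPercentDifference(0, 1), "zero")
  expect_true(is.na(out))
})

test_that("folds partition the animals with the stated training fraction", {
  ids <- sprintf("R%02d", 1:66)
  fs <- makeFolds(ids, k = 10, trainFraction = 0.66, seed = 3)
  tests <- lapply(fs$folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), sort(ids))     # union = all animals
  expect_identical(anyDuplicated(unlist(tests)), 0L)   # pairwise disjoint
  for (f in fs$folds) {
    expect_length(intersect(f$train, f$test), 0)       # no leakage
    expect_length(f$train, round(0.66 * 66))           # 44 of 66
  }
  fs2 <- makeFolds(ids, k = 10, trainFraction = 0.66, seed = 3)
  expect_identical(fs, fs2)
  expect_error(makeFolds(ids[1:5], k = 10), "exceed")
  expect_error(makeFolds(c("a", "a", "b"), k = 2), "unique")
})

test_that("bootstrap confidence intervals behave and roughly cover", {
  expect_equal(confidenceInterval(rep(2.5, 6)), c(2.5, 2.5))
  expect_equal(confidenceInterval(3.1), c(3.1, 3.1))
  set.seed(6)
  v <- rnorm(200)
  ci <- confidenceInterval(v, nBoot = 4000, seed = 1)
  expect_lt(ci[1], mean(v)); expect_gt(ci[2], mean(v))
  # approximate symmetry around the mean for symmetric data
  expect_equal(mean(v) - ci[1], ci[2] - mean(v), tolerance = 0.25)

  # coverage over replications of normal fold means (percentile bootstrap
  # slightly undercovers at small n, so the band is one-sided generous)
  set.seed(9)
  hits <- vapply(1:400, function(i) {
    x <- rnorm(20, mean = 1, sd = 1)
    ci <- confidenceInterval(x, nBoot = 800, seed = i)
    ci[1] <= 1 && 1 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.86)
  expect_lte(mean(hits), 0.99)
})

test_that("nested CV on a small noiseless cohort reaches near-perfect Dice", {
  g <- smallGrid()
  a <- smallAIF(g)
  spec <- phantomSpec(dim = c(12L, 12L, 1L), coreRadius = 2.5,
                      rimRadius = 4.5, noiseSd = 0)
  co <- makeCohort(6, spec, g, a, seed = 11)
  cfg <- somConfig(orderingSteps = 40L, maxEpochs = 100L)
  rep <- suppressWarnings(
    runNestedCV(co, k = 3, somCfg = cfg, seed = 11, nBoot = 500))
  expect_gte(rep@summary$dsc_m2$mean, 0.95)
  expect_gte(rep@summary$dsc_m3$mean, 0.95)
  expect_identical(nrow(rep@perFold), 3L)
  expect_true(all(rep@perFold$dscM2 >= 0 & rep@perFold$dscM2 <= 1))
  s <- rep@summary
  expect_lte(s$dsc_m2$ci[1], s$dsc_m2$mean)
  expect_gte(s$dsc_m2$ci[2], s$dsc_m2$mean)
})

test_that("shuffled training labels collapse region agreement to chance", {
  st <- smallStudy(noiseSd = 0.02, dim = c(16L, 16L, 1L))
  g <- acqGrid(st)
  res <- fitVolume(st)
  prof <- excludeAndNormalize(
    matrix(st@dr1, prod(dim(st@mask)), nFrames(g))[which(st@mask), ], g)
  labs <- res@labelMap[res@mask]
  cfg <- somConfig(orderingSteps = 20L, maxEpochs = 50L)
  som <- batchTrain(prof, cfg)
  set.seed(123)
  tabShuf <- neuronProbabilities(
    computeHitMap(som, prof, sample(labs)), som)
  pv <- voxelProbabilities(st, som, tabShuf, tau = 0.5)
  # with ~76/8/16% label mix no neuron should favor model 2 or 3 at 50%:
  # agreement for the leaky regions falls to (or near) zero
  dsc2 <- dice(regionMasks(pv)[[2]], res@labelMap == 2 & res@mask)
  dsc3 <- dice(regionMasks(pv)[[3]], res@labelMap == 3 & res@mask)
  frac <- tabulate(labs, 3) / length(labs)
  chance <- 2 * frac / (1 + frac)   # dice of a random subset against itself
  expect_lt(dsc2, max(0.2, chance[2] + 0.1))
  expect_lt(dsc3, max(0.2, chance[3] + 0.1))
})

test_that("evaluation reports serialize to CSV and JSON", {
  g <- smallGrid()
  a <- smallAIF(g)
  spec <- phantomSpec(dim = c(10L, 10L, 1L), coreRadius = 2, rimRadius = 3.5,
                      noiseSd = 0.05)
  co <- makeCohort(4, spec, g, a, seed = 2)
  cfg <- somConfig(orderingSteps = 10L, maxEpochs = 25L)
  rep <- suppressWarnings(
    runNestedCV(co, k = 2, somCfg = cfg, seed = 2, nBoot = 200))
  dir <- file.path(tempdir(), "evalrep")
  writeEvaluationReport(rep, dir)
  folds <- read.csv(file.path(dir, "evaluation_folds.csv"))
  expect_identical(nrow(folds), 2L)
  js <- jsonlite::read_json(file.path(dir, "evaluation_summary.json"),
                            simplifyVector = TRUE)
  expect_true(all(c("dsc_m2", "dsc_m3", "vp", "ktrans", "ve", "mpd") %in%
                  names(js)))
})
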