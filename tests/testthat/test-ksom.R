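test_that("hexagonal lattice distances match hand-computed geometry", {
  g12 <- hexDistances(somConfig(rows = 1, cols = 2))
  expect_equal(gridDistances(g12)[1, 2], 1)

  # 2 x 2 offset-row hex: coordinates (0,0), (1,0), (0.5, s), (1.5, s) with
  # s = sqrt(3)/2; six pairwise distances enumerated by hand
  g22 <- hexDistances(somConfig(rows = 2, cols = 2))
  d <- gridDistances(g22)
  expect_equal(d[1, 2], 1)
  expect_equal(d[1, 3], 1)
  expect_equal(d[1, 4], sqrt(3))
  expect_equal(d[2, 3], 1)
  expect_equal(d[2, 4], 1)
  expect_equal(d[3, 4], 1)

  g88 <- hexDistances(somConfig())
  expect_identical(nrow(gridCoords(g88)), 64L)
  expect_lt(max(gridDistances(g88)), 11)
  # interior neurons have nearest neighbors at exactly 1
  dd <- gridDistances(g88); diag(dd) <- Inf
  expect_equal(unname(apply(dd, 1, min)), rep(1, 64))
})

test_that("linear initialization is deterministic and spans the data plane", {
  cfg <- somConfig(rows = 4, cols = 4)
  set.seed(9)
  dir <- rnorm(10)
  line <- outer(seq(-1, 1, length.out = 50), dir) +
    matrix(rnorm(10), 50, 10, byrow = TRUE)
  W <- initWeights(line, cfg)
  # rank-1 data: all prototypes lie on the data line
  ctr <- colMeans(line)
  resid <- sweep(W, 2, ctr)
  proj <- resid - outer(drop(resid %*% dir) / sum(dir^2), dir)
  expect_lt(max(abs(proj)), 1e-6)

  set.seed(10)
  X <- rbind(matrix(rnorm(200, 0), 20), matrix(rnorm(200, 4), 20))
  expect_identical(initWeights(X, cfg), initWeights(X, cfg))

  # prototypes lie in the principal plane found independently by prcomp
  W2 <- initWeights(X, cfg)
  pc <- prcomp(X, rank. = 2)
  resid <- sweep(W2, 2, colMeans(X))
  proj <- resid %*% pc$rotation %*% t(pc$rotation)
  expect_lt(max(abs(resid - proj)), 1e-8)

  expect_error(initWeights(matrix(1, 5, 4), cfg), "identical")
  expect_error(initWeights(X[1, , drop = FALSE], cfg), "2 profiles")
})

test_that("BMU lookup matches a brute-force scan and breaks ties low", {
  set.seed(4)
  W <- matrix(rnorm(64 * 12), 64)
  expect_identical(findBMU(W, W[17, ]), 17L)
  # two equidistant prototypes: lower index wins
  Wt <- rbind(c(0, 0), c(2, 0))
  expect_identical(findBMU(Wt, c(1, 0)), 1L)

  X <- matrix(rnorm(30 * 12), 30)
  brute <- apply(X, 1, function(x)
    which.min(colSums((t(W) - x)^2)))
  expect_identical(findBMU(W, X), as.integer(brute))

  expect_error(findBMU(W, c(1, NA, rep(0, 10))), "finite")
  expect_error(findBMU(W, rnorm(5)), "dimension")
})

test_that("batch training reaches fixed points and reduces quantization error", {
  cfg <- somConfig(rows = 3, cols = 3, orderingSteps = 10, maxEpochs = 40)
  # single repeated profile: every prototype converges to it
  p <- rnorm(8)
  m <- batchTrain(matrix(p, 20, 8, byrow = TRUE), cfg)
  expect_lt(max(abs(sweep(somWeights(m), 2, p))), 1e-6)
  expect_true(m@converged)

  set.seed(12)
  X <- matrix(rnorm(400), 50, 8)
  W0 <- initWeights(X, cfg)
  m2 <- batchTrain(X, cfg)
  expect_lte(quantizationError(m2, X), quantizationError(W0, X))

  expect_error(batchTrain(X[0, ], cfg), "empty")
})

test_that("well-separated clusters occupy disjoint neuron subsets", {
  set.seed(31)
  cfg <- somConfig(rows = 4, cols = 4, orderingSteps = 20, maxEpochs = 60)
  X <- rbind(matrix(rnorm(150, 0, 0.1), 30),
             matrix(rnorm(150, 3, 0.1), 30),
             matrix(rnorm(150, -3, 0.1), 30))
  m <- batchTrain(X, cfg)
  bmu <- findBMU(m, X)
  sets <- split(bmu, rep(1:3, each = 30))
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  expect_length(intersect(sets[[1]], sets[[3]]), 0)
  expect_length(intersect(sets[[2]], sets[[3]]), 0)
})

test_that("training is deterministic and preserves topology on a kep sweep", {
  g <- smallGrid()
  a <- smallAIF(g)
  keps <- seq(0.3, 2.5, length.out = 80)
  prof <- t(vapply(keps, function(k)
    evalModel(pkParams(0.01, 0.15, k, 3L), a, g), numeric(nFrames(g))))
  prof <- excludeAndNormalize(prof, g)
  cfg <- somConfig()
  m1 <- batchTrain(prof, cfg)
  m2 <- batchTrain(prof, cfg)
  expect_identical(somWeights(m1), somWeights(m2))
  bmu <- findBMU(m1, prof)
  expect_identical(bmu, findBMU(m2, prof))

  # neighbors along the 1-parameter family stay close on the lattice
  D <- gridDistances(m1)
  adjacent <- D[cbind(bmu[-length(bmu)], bmu[-1])]
  expect_gte(mean(adjacent <= 2), 0.9)
})

test_that("hit maps tally BMUs exactly and conserve counts", {
  set.seed(8)
  W <- matrix(rnorm(9 * 6), 9)
  cfgW <- somConfig(rows = 3, cols = 3)
  X <- matrix(rnorm(40 * 6), 40)
  labels <- sample(1:3, 40, replace = TRUE)
  hm <- computeHitMap(W, X, labels)
  expect_identical(sum(totalHits(hm)), 40L)
  bmu <- findBMU(W, X)
  for (l in 1:3)
    expect_identical(hitCounts(hm)[, l], tabulate(bmu[labels == l], 9))

  # all profiles on one prototype
  X1 <- matrix(rep(W[5, ], 7), 7, byrow = TRUE)
  hm1 <- computeHitMap(W, X1, rep(2L, 7))
  expect_identical(totalHits(hm1)[5], 7L)
  expect_identical(sum(hitCounts(hm1)[, 1]), 0L)  # empty label row

  expect_error(computeHitMap(W, X, sample(4:5, 40, TRUE)), "labels")
  expect_error(computeHitMap(W, X, labels[-1]), "length")
  expect_silent(writeHitMapCsv(hm, cfgW, tempfile(fileext = ".csv")))
})

test_that("quantization error equals its direct recomputation", {
  set.seed(13)
  W <- matrix(rnorm(8 * 5), 8)
  X <- matrix(rnorm(25 * 5), 25)
  direct <- mean(apply(X, 1, function(x)
    sqrt(min(colSums((t(W) - x)^2)))))
  expect_equal(quantizationError(W, X), direct, tolerance = 1e-12)
  # prototypes equal to the data: zero error
  expect_equal(quantizationError(X[1:8, ], X[1:8, ]), 0)
  # a single prototype: mean distance to it
  W1 <- matrix(0, 1, 5)
  expect_equal(quantizationError(W1, X), mean(sqrt(rowSums(X^2))),
               tolerance = 1e-12)
})

test_that("a trained SOM round-trips through its JSON container", {
  set.seed(14)
  X <- matrix(rnorm(200), 40, 5)
  cfg <- somConfig(rows = 3, cols = 2, orderingSteps = 5, maxEpochs = 10)
  m <- batchTrain(X, cfg)
  path <- tempfile(fileext = ".json")
  writeSOM(m, path)
  m2 <- readSOM(path)
  expect_equal(somWeights(m2), somWeights(m), tolerance = 1e-12)
  expect_identical(m2@config@rows, m@config@rows)
  expect_identical(m2@epochsTrained, m@epochsTrained)
})
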