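test_that("Model-1 fit recovers vp and handles degenerate input", {
  g <- smallGrid()
  a <- smallAIF(g)
  tr <- evalModel(pkParams(0.03, modelOrder = 1), a, g)
  f <- fitModel1(tr, a, g)
  expect_equal(f@params@vp, 0.03, tolerance = 1e-12)
  expect_lt(f@rss, 1e-20)
  expect_identical(f@nFree, 1L)
  expect_identical(f@nObs, length(retainedIndices(g)))

  # trace orthogonal to the retained AIF: vp = 0, rss = ||trace||^2
  idx <- retainedIndices(g)
  x <- aifValues(a)[idx]
  set.seed(3)
  y <- rnorm(length(idx))
  y <- y - sum(y * x) / sum(x * x) * x
  tr0 <- rep(0, nFrames(g)); tr0[idx] <- y
  f0 <- fitModel1(tr0, a, g)
  expect_equal(f0@params@vp, 0)
  expect_equal(f0@rss, sum(y^2), tolerance = 1e-10)

  expect_error(fitModel1(tr, rep(0, nFrames(g)), g), "degenerate")
})

test_that("Model-1/2 fits agree with explicit normal-equation oracles", {
  g <- smallGrid()
  a <- smallAIF(g)
  idx <- retainedIndices(g)
  av <- aifValues(a)
  set.seed(21)
  for (i in 1:5) {
    tr <- evalModel(pkParams(runif(1, .01, .04), runif(1, .05, .3), 0, 2L),
                    a, g) + rnorm(nFrames(g), sd = 0.01)
    y <- tr[idx]
    # oracle: pseudo-inverse on the design [AIF, cumint(AIF)]
    X <- cbind(av[idx], cumulativeIntegral(av, g)[idx])
    beta <- solve(crossprod(X), crossprod(X, y))
    f1 <- fitModel1(tr, a, g)
    expect_equal(f1@params@vp, max(sum(X[, 1] * y) / sum(X[, 1]^2), 0),
                 tolerance = 1e-10)
    f2 <- fitModel2(tr, a, g)
    expect_equal(f2@params@vp, beta[1], tolerance = 1e-8)
    expect_equal(f2@params@ktrans, beta[2] * 60, tolerance = 1e-8)
    expect_equal(f2@rss, sum((y - X %*% beta)^2), tolerance = 1e-8)
  }
})

test_that("Model-2 fit is exact on noiseless data and nests Model 1", {
  g <- smallGrid()
  a <- smallAIF(g)
  tr <- evalModel(pkParams(0.02, 0.14, 0, 2L), a, g)
  f <- fitModel2(tr, a, g)
  expect_equal(f@params@vp, 0.02, tolerance = 1e-9)
  expect_equal(f@params@ktrans, 0.14, tolerance = 1e-9)

  tr1 <- evalModel(pkParams(0.02, modelOrder = 1), a, g)
  f2 <- fitModel2(tr1, a, g)
  f1 <- fitModel1(tr1, a, g)
  expect_equal(f2@params@ktrans, 0, tolerance = 1e-9)
  expect_lt(abs(f2@rss - f1@rss), 1e-12 + 1e-8 * f1@rss)
})

test_that("Model-3 separable fit recovers parameters and respects nesting", {
  g <- smallGrid()
  a <- smallAIF(g)
  tr <- evalModel(pkParams(0.01, 0.165, 1.0, 3L), a, g)
  f <- fitModel3(tr, a, g)
  expect_equal(f@params@vp, 0.01, tolerance = 1e-4)
  expect_equal(f@params@ktrans, 0.165, tolerance = 1e-4)
  expect_equal(f@params@kep, 1.0, tolerance = 1e-4)

  expect_error(fitModel3(tr, a, g, kepBounds = c(5, 1e-3)), "increasing")

  # kep truth at the lower bound: rss3 still <= rss2
  trlo <- evalModel(pkParams(0.02, 0.1, 1e-3, 3L), a, g)
  f3 <- fitModel3(trlo, a, g)
  f2 <- fitModel2(trlo, a, g)
  expect_lte(f3@rss, f2@rss + 1e-15)
})

test_that("Model-3 kep agrees with a dense profile-likelihood grid oracle", {
  g <- smallGrid()
  a <- smallAIF(g)
  av <- aifValues(a)
  idx <- retainedIndices(g)
  x1 <- av[idx]
  kgrid <- exp(seq(log(1e-3), log(5), length.out = 500))
  profRss <- function(y) {
    vapply(kgrid, function(k) {
      ck <- expConvolution(av, k, g)[idx]
      X <- cbind(x1, ck)
      b <- solve(crossprod(X), crossprod(X, y))
      sum((y - X %*% b)^2)
    }, numeric(1))
  }
  set.seed(5)
  for (i in 1:12) {
    truth <- pkParams(runif(1, .005, .04), runif(1, .05, .3),
                      runif(1, .3, 3), 3L)
    tr <- evalModel(truth, a, g)
    f <- fitModel3(tr, a, g)
    kOracle <- kgrid[which.min(profRss(tr[idx]))]
    step <- log(kgrid[2]) - log(kgrid[1])
    expect_lt(abs(log(f@params@kep) - log(kOracle)), step + 1e-9)
  }
})

test_that("sequential F-test selection labels the nested hierarchy", {
  g <- smallGrid()
  a <- smallAIF(g)
  # equal rss at every order: F = 0 twice, label 1
  tr <- evalModel(pkParams(0.03, modelOrder = 1), a, g)
  r <- fitVoxel(tr, a, g)
  expect_identical(r@label, 1L)
  # huge improvements (noiseless Model 3): label 3
  tr3 <- evalModel(pkParams(0.01, 0.2, 1.2, 3L), a, g)
  expect_identical(fitVoxel(tr3, a, g)@label, 3L)
  # noiseless Model 2: label 2
  tr2 <- evalModel(pkParams(0.02, 0.15, 0, 2L), a, g)
  expect_identical(fitVoxel(tr2, a, g)@label, 2L)

  # rss ordering violation is a contract error
  f1 <- fitModel1(tr2, a, g)
  f2 <- fitModel2(tr2, a, g)
  f3 <- fitModel3(tr2, a, g)
  broken <- f2
  broken@rss <- f1@rss + 1
  expect_error(selectModel(list(f1, broken, f3), 0.95), "contract")
  expect_error(selectModel(list(f2, f1, f3)), "ordered")
})

test_that("fitVolume matches the per-voxel pipeline and rss is monotone", {
  st <- smallStudy(noiseSd = 0.05)
  g <- acqGrid(st)
  res <- fitVolume(st)
  # single-voxel mask reproduces fitVoxel exactly
  m1 <- array(FALSE, dim(st@mask)); m1[7, 9, 1] <- TRUE
  single <- fitVolume(st@dr1, m1, st@aif)
  vox <- fitVoxel(st@dr1[7, 9, 1, ], st@aif, g)
  expect_identical(single@labelMap[7, 9, 1], vox@label)
  expect_equal(paramMap(single, "vpM2")[7, 9, 1],
               vox@fits[[2]]@params@vp, tolerance = 1e-12)
  expect_equal(paramMap(single, "kepM3")[7, 9, 1],
               vox@fits[[3]]@params@kep, tolerance = 1e-9)
  expect_equal(paramMap(single, "rss3")[7, 9, 1], vox@fits[[3]]@rss,
               tolerance = 1e-10)

  # nesting monotonicity across every voxel
  msk <- res@mask
  expect_true(all(paramMap(res, "rss2")[msk] <=
                  paramMap(res, "rss1")[msk] + 1e-10))
  expect_true(all(paramMap(res, "rss3")[msk] <=
                  paramMap(res, "rss2")[msk] + 1e-10))

  expect_error(fitVolume(st@dr1, array(FALSE, dim(st@mask)), st@aif),
               "empty")
  expect_error(fitVolume(st@dr1, array(TRUE, c(2, 2, 2)), st@aif), "mask")
})

test_that("noisy volume fits recover per-region parameters", {
  st <- smallStudy(noiseSd = 0.05, dim = c(16L, 16L, 1L))
  res <- fitVolume(st)
  lab <- st@labels
  medRelErr <- function(est, tru, sel) {
    i <- sel & is.finite(tru) & tru > 0
    median(abs(est[i] - tru[i]) / tru[i])
  }
  expect_lt(medRelErr(paramMap(res, "vpM1"), st@truth$vp, lab == 1), 0.10)
  expect_lt(medRelErr(paramMap(res, "ktransM3"), st@truth$ktrans, lab == 3),
            0.10)
  expect_lt(medRelErr(paramMap(res, "kepM3"), st@truth$kep, lab == 3), 0.10)
})
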