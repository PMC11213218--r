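test_that("the simulated AIF honors its contracts", {
  g <- smallGrid()
  a <- makeAIF(g, peak = 2.5)
  v <- aifValues(a)
  expect_true(all(v[seq_len(injectionIndex(g) - 1L)] == 0))
  expect_equal(max(v), 2.5, tolerance = 1e-9)
  expect_lt(v[nFrames(g)], 0.2 * max(v))
  # closed-form gamma-variate check at the peak frame
  t0 <- timePoints(g)[injectionIndex(g)]
  tau <- timePoints(g) - t0
  bolus <- ifelse(tau > 0, (tau / 12)^3 * exp(3 * (1 - tau / 12)), 0)
  expect_equal(which.max(v), which.max(bolus))
  expect_error(makeAIF(g, alpha = -1), "positive")
})

test_that("simulated studies reproduce the forward models exactly when noiseless", {
  st <- smallStudy(noiseSd = 0)
  g <- acqGrid(st)
  lab <- st@labels
  pick <- function(l) which(lab == l)[1]
  for (l in 1:3) {
    j <- pick(l)
    ijk <- arrayInd(j, dim(lab))
    p <- pkParams(st@truth$vp[j],
                  if (l >= 2) st@truth$ktrans[j] else 0,
                  if (l == 3) st@truth$kep[j] else 0, as.integer(l))
    expect_equal(st@dr1[ijk[1], ijk[2], ijk[3], ], evalModel(p, st@aif, g),
                 tolerance = 1e-12)
  }
  # determinism
  st2 <- smallStudy(noiseSd = 0)
  expect_identical(st@dr1, st2@dr1)
  expect_identical(st@truth, st2@truth)
})

test_that("injected noise matches the configured level", {
  st <- smallStudy(noiseSd = 0.05, dim = c(16L, 16L, 1L))
  noiseless <- smallStudy(noiseSd = 0, dim = c(16L, 16L, 1L))
  resid <- st@dr1 - noiseless@dr1
  peak <- max(abs(noiseless@dr1))
  expect_equal(sd(resid), 0.05 * peak, tolerance = 0.05)
})

test_that("normalization is scale-invariant, unit-peak and idempotent", {
  st <- smallStudy(noiseSd = 0.02)
  g <- acqGrid(st)
  tr <- st@dr1[6, 6, 1, ]
  n1 <- excludeAndNormalize(tr, g)
  expect_equal(max(abs(n1)), 1)
  expect_equal(excludeAndNormalize(5.7 * tr, g), n1, tolerance = 1e-12)
  # idempotence on the already-normalized (retained-frame) profile
  n2 <- excludeAndNormalize(n1, g)
  expect_equal(as.numeric(n2), as.numeric(n1), tolerance = 1e-12)
  # all-zero trace flagged
  z <- excludeAndNormalize(rep(0, nFrames(g)), g)
  expect_true(all(z == 0))
  expect_true(attr(z, "excluded"))
  # unit-energy variant
  l2 <- excludeAndNormalize(tr, g, method = "l2")
  expect_equal(sum(l2^2), 1, tolerance = 1e-12)
})

test_that("normalized exemplars of the three models order by terminal kinetics", {
  g <- smallGrid(300L)
  a <- makeAIF(g)
  trs <- rbind(evalModel(pkParams(0.02, modelOrder = 1), a, g),
               evalModel(pkParams(0.02, 0.15, 0, 2L), a, g),
               evalModel(pkParams(0.02, 0.15, 1.5, 3L), a, g))
  np <- excludeAndNormalize(trs, g)
  nc <- ncol(np)
  slope <- function(x, i) unname(coef(lm(x[i] ~ i))[2])
  late <- (nc - 60):nc
  sM1 <- slope(np[1, ], late)
  sM2 <- slope(np[2, ], late)
  sM3 <- slope(np[3, ], late)
  aifn <- excludeAndNormalize(aifValues(a), g)
  expect_lt(sM1, 0)                                # follows the AIF washout
  expect_equal(sM1, slope(aifn[1, ], late), tolerance = 1e-6)
  expect_gt(sM2, 0)                                # unidirectional ramp
  # Model 3 is sub-linear: back-flux caps the uptake, so its terminal slope
  # falls below the Model-2 ramp (and below zero once washout dominates)
  expect_lt(sM3, sM2)
  expect_lt(sM3, 0)
})

test_that("cohorts are reproducible with label proportions set by geometry", {
  g <- smallGrid()
  a <- smallAIF(g)
  spec <- phantomSpec(dim = c(16L, 16L, 2L), coreRadius = 3, rimRadius = 5,
                      noiseSd = 0.05)
  co <- makeCohort(10, spec, g, a, seed = 4)
  expect_length(co, 10)
  expect_identical(anyDuplicated(vapply(co, function(s) s@animalId,
                                        character(1))), 0L)
  co2 <- makeCohort(10, spec, g, a, seed = 4)
  expect_identical(co[[3]]@dr1, co2[[3]]@dr1)
  expect_false(identical(co[[1]]@dr1, co[[2]]@dr1))

  # profile count conservation
  expect_identical(sum(vapply(co, function(s) sum(s@mask), integer(1))),
                   10L * 16L * 16L * 2L)

  # expected label fractions from disc areas (jitter leaves areas unchanged)
  labs <- unlist(lapply(co, function(s) s@labels[s@mask]))
  fr <- tabulate(labs, 3) / length(labs)
  area <- 16 * 16
  expCore <- pi * 3^2 / area
  expRim <- pi * (5^2 - 3^2) / area
  expect_equal(fr[2], expCore, tolerance = 0.25)
  expect_equal(fr[3], expRim, tolerance = 0.25)
  expect_gt(fr[1], 0.5)
})

test_that("noiseless studies round-trip through NMS exactly", {
  st <- smallStudy(noiseSd = 0, dim = c(14L, 14L, 1L))
  res <- fitVolume(st)
  expect_identical(res@labelMap, st@labels)
  lab <- st@labels
  relErr <- function(est, tru, sel) {
    i <- sel & is.finite(tru) & tru > 0
    max(abs(est[i] - tru[i]) / tru[i])
  }
  vpSel <- nmsSelectedMaps(res)@vp / 100
  expect_lt(relErr(vpSel, st@truth$vp, st@mask), 1e-3)
  expect_lt(relErr(paramMap(res, "ktransM2"), st@truth$ktrans, lab == 2), 1e-3)
  expect_lt(relErr(paramMap(res, "ktransM3"), st@truth$ktrans, lab == 3), 1e-3)
  expect_lt(relErr(paramMap(res, "kepM3"), st@truth$kep, lab == 3), 1e-3)
})
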