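## Conventional nested model selection (NMS).
##
## Per voxel, the three nested models are fit by least squares on the
## retained frames: Model 1 is a no-intercept regression of the trace on the
## AIF, Model 2 adds the running AIF integral as a second design column, and
## Model 3 replaces that column with the exponential convolution, profiled
## over Kep (separable least squares: linear in vp and Ktrans for fixed Kep,
## coarse log-spaced search plus local refinement over Kep).
##
## Selection is by sequential partial F-tests (1 -> 2, then 2 -> 3 if
## rejected), each with 1 numerator dof, at a stated confidence level. The
## F-tests use the unconstrained RSS (which is non-increasing in model order
## by construction); reported parameters are clipped at zero with the free
## column refit. An RSS improvement below 1e-11 x (total sum of squares) is
## treated as numerically zero so that noiseless data cannot trigger
## spurious rejections through rounding error.

.RSS_FLOOR_REL <- 1e-11

## Constrained (non-negative) 2-parameter estimates given unconstrained b1,
## b2 and the sufficient statistics. Clip the negative coefficient and refit
## the other column alone.
.clipRefit2 <- function(b1, b2, x1y, x2y, s11, s22) {
  vp <- b1
  kt <- b2
  bad2 <- kt < 0
  vp[bad2] <- pmax(x1y[bad2] / s11, 0)
  kt[bad2] <- 0
  bad1 <- !bad2 & vp < 0
  vp[bad1] <- 0
  kt[bad1] <- pmax(x2y[bad1] / s22[bad1], 0)
  list(vp = pmax(vp, 0), kt = pmax(kt, 0))
}

## Vectorized fit of all three models. Y holds the *retained* frames of the
## traces, one voxel per column. kep unit: 1/min.
.fitCore <- function(Y, aifv, grid, kepBounds = c(1e-3, 5), nCoarse = 60L,
                     refine = TRUE, withM3 = TRUE) {
  if (length(kepBounds) != 2L || kepBounds[1] <= 0 ||
      kepBounds[2] <= kepBounds[1])
    stop("kepBounds must be an increasing positive interval")
  idx <- retainedIndices(grid)
  nObs <- length(idx)
  if (nrow(Y) != nObs) .contract("trace rows must be the retained frames")
  V <- ncol(Y)
  x1 <- aifv[idx]
  x2 <- cumulativeIntegral(aifv, grid)[idx]
  s11 <- sum(x1 * x1)
  if (s11 == 0) .degenerate("AIF is zero over the retained frames")
  tss <- colSums(Y * Y)
  x1y <- drop(crossprod(x1, Y))

  ## Model 1
  vp1u <- x1y / s11
  rss1 <- pmax(tss - vp1u^2 * s11, 0)
  vp1 <- pmax(vp1u, 0)

  ## Model 2
  x2y <- drop(crossprod(x2, Y))
  s12 <- sum(x1 * x2)
  s22 <- sum(x2 * x2)
  det2 <- s11 * s22 - s12^2
  if (det2 <= 1e-12 * s11 * s22)
    .degenerate("AIF and its running integral are collinear")
  b1 <- (s22 * x1y - s12 * x2y) / det2
  b2 <- (-s12 * x1y + s11 * x2y) / det2
  rss2 <- pmax(tss - (b1 * x1y + b2 * x2y), 0)
  cons2 <- .clipRefit2(b1, b2, x1y, x2y, s11, rep(s22, V))

  if (!withM3)
    return(list(nObs = nObs, tss = tss, vp1 = vp1, rss1 = rss1,
                vp2 = cons2$vp, ktrans2 = cons2$kt * 60, rss2 = rss2))

  ## Model 3: profile over kep. A kep = 0 candidate (the Model-2 design) is
  ## included so rss3 <= rss2 holds exactly; ties go to the smallest kep.
  keps <- c(0, exp(seq(log(kepBounds[1]), log(kepBounds[2]),
                       length.out = nCoarse)))
  nCand <- length(keps)
  convCols <- matrix(0, nObs, nCand)
  convCols[, 1] <- x2
  for (i in 2:nCand)
    convCols[, i] <- expConvolution(aifv, keps[i], grid)[idx]
  c1 <- drop(crossprod(x1, convCols))          # <x1, ck> per candidate
  c2 <- colSums(convCols * convCols)           # <ck, ck>
  CY <- crossprod(convCols, Y)                 # nCand x V
  detK <- s11 * c2 - c1^2
  B1 <- (c2 * (rep(x1y, each = nCand)) - c1 * CY) / detK
  B2 <- (s11 * CY - c1 * rep(x1y, each = nCand)) / detK
  rssAll <- pmax(sweep(-(B1 * rep(x1y, each = nCand) + B2 * CY),
                       2, tss, "+"), 0)
  best <- max.col(-t(rssAll), ties.method = "first")
  sel <- cbind(best, seq_len(V))
  kep3 <- keps[best]
  rss3 <- rssAll[sel]
  vp3u <- B1[sel]
  kt3u <- B2[sel]
  c2b <- c2[best]
  cyb <- CY[sel]

  if (refine) {
    logk <- log(keps[-1])
    for (j in which(best > 1L)) {
      b <- best[j]
      lo <- if (b <= 2L) logk[1] else logk[b - 2L]
      hi <- if (b >= nCand) logk[nCand - 1L] else logk[b]
      y <- Y[, j]
      x1yj <- x1y[j]
      obj <- function(lk) {
        ck <- expConvolution(aifv, exp(lk), grid)[idx]
        t12 <- sum(x1 * ck)
        t22 <- sum(ck * ck)
        cy <- sum(ck * y)
        dk <- s11 * t22 - t12^2
        bb1 <- (t22 * x1yj - t12 * cy) / dk
        bb2 <- (s11 * cy - t12 * x1yj) / dk
        tss[j] - (bb1 * x1yj + bb2 * cy)
      }
      op <- stats::optimize(obj, c(lo, hi), tol = 1e-4)
      if (op$objective < rss3[j]) {
        kep3[j] <- exp(op$minimum)
        ck <- expConvolution(aifv, kep3[j], grid)[idx]
        t12 <- sum(x1 * ck)
        t22 <- sum(ck * ck)
        cy <- sum(ck * y)
        dk <- s11 * t22 - t12^2
        vp3u[j] <- (t22 * x1yj - t12 * cy) / dk
        kt3u[j] <- (s11 * cy - t12 * x1yj) / dk
        rss3[j] <- max(op$objective, 0)
        c2b[j] <- t22
        cyb[j] <- cy
      }
    }
  }
  cons3 <- .clipRefit2(vp3u, kt3u, x1y, cyb, s11, c2b)

  list(nObs = nObs, tss = tss,
       vp1 = vp1, rss1 = rss1,
       vp2 = cons2$vp, ktrans2 = cons2$kt * 60, rss2 = rss2,
       vp3 = cons3$vp, ktrans3 = cons3$kt * 60, kep3 = kep3, rss3 = rss3)
}

## Sequential partial F-tests, vectorized. Returns integer labels.
.selectLabels <- function(rss1, rss2, rss3, tss, nObs, confidenceLevel) {
  floorv <- .RSS_FLOOR_REL * tss
  crit1 <- stats::qf(confidenceLevel, 1, nObs - 2L)
  crit2 <- stats::qf(confidenceLevel, 1, nObs - 3L)
  d12 <- pmax(rss1 - rss2, 0)
  d23 <- pmax(rss2 - rss3, 0)
  f1 <- ifelse(rss2 > 0, d12 / (rss2 / (nObs - 2L)), Inf)
  f2 <- ifelse(rss3 > 0, d23 / (rss3 / (nObs - 3L)), Inf)
  sig1 <- d12 > floorv & f1 > crit1
  sig2 <- sig1 & d23 > floorv & f2 > crit2
  as.integer(1L + sig1 + sig2)
}

.retainedTrace <- function(trace, grid) {
  y <- as.numeric(trace)
  if (length(y) != nFrames(grid)) .contract("trace and grid lengths differ")
  if (any(!is.finite(y))) stop("trace must be finite")
  matrix(y[retainedIndices(grid)], ncol = 1)
}

.mkFit <- function(order, vp, ktrans, kep, rss, tss, nObs) {
  new("ModelFit", modelOrder = as.integer(order),
      params = pkParams(vp, ktrans, kep, order),
      rss = rss, tss = tss, nFree = as.integer(order), nObs = as.integer(nObs))
}

#' Fit the vascular-only model (Model 1)
#'
#' No-intercept least-squares regression of the retained tissue trace on the
#' retained AIF: vp = sum(C_t C_a) / sum(C_a^2), clipped at zero for
#' reporting (the stored RSS is the unconstrained one).
#'
#' @param trace numeric tissue delta-R1 trace on the full grid.
#' @param aif an [AIFCurve-class] or numeric vector on `grid`.
#' @param grid a [TimeGrid-class].
#' @return a [ModelFit-class].
#' @export
fitModel1 <- function(trace, aif, grid) {
  Y <- .retainedTrace(trace, grid)
  v <- .aifVals(aif)
  x1 <- v[retainedIndices(grid)]
  s11 <- sum(x1 * x1)
  if (s11 == 0) .degenerate("AIF is zero over the retained frames")
  tss <- sum(Y^2)
  vpu <- sum(x1 * Y) / s11
  rss <- max(tss - vpu^2 * s11, 0)
  .mkFit(1L, max(vpu, 0), 0, 0, rss, tss, nrow(Y))
}

#' Fit the leakage-without-back-flux model (Model 2)
#'
#' Two-parameter linear least squares on design columns (AIF, running AIF
#' integral). Non-negativity of the reported vp and Ktrans is enforced by
#' clipping and refitting the free column.
#'
#' @inheritParams fitModel1
#' @return a [ModelFit-class] (ktrans in 1/min).
#' @export
fitModel2 <- function(trace, aif, grid) {
  Y <- .retainedTrace(trace, grid)
  r <- .fitCore(Y, .aifVals(aif), grid, refine = FALSE, withM3 = FALSE)
  .mkFit(2L, r$vp2, r$ktrans2, 0, r$rss2, r$tss, r$nObs)
}

#' Fit the leakage-with-back-flux model (Model 3)
#'
#' Separable least squares: for fixed Kep the model is linear in (vp,
#' Ktrans); Kep is found by a coarse search over log-spaced candidates in
#' `kepBounds` (plus the Kep = 0 limit, i.e. Model 2) followed by bounded
#' local refinement. Ties go to the smallest Kep.
#'
#' @inheritParams fitModel1
#' @param kepBounds numeric(2), Kep search bounds in 1/min
#'   (default c(1e-3, 5)).
#' @param nCoarse number of log-spaced coarse candidates (default 60).
#' @return a [ModelFit-class] (ktrans, kep in 1/min).
#' @export
fitModel3 <- function(trace, aif, grid, kepBounds = c(1e-3, 5),
                      nCoarse = 60L) {
  Y <- .retainedTrace(trace, grid)
  r <- .fitCore(Y, .aifVals(aif), grid, kepBounds, nCoarse)
  .mkFit(3L, r$vp3, r$ktrans3, r$kep3, r$rss3, r$tss, r$nObs)
}

#' Select the supported nested model for one voxel
#'
#' Sequential partial F-tests on the three nested fits: Model 1 vs 2, then
#' (only if rejected) Model 2 vs 3, each with one numerator degree of
#' freedom. The label is the highest order whose additional parameter was
#' significant at level `1 - confidenceLevel`.
#'
#' @param fits list of three [ModelFit-class] objects (orders 1, 2, 3).
#' @param confidenceLevel confidence level, default 0.95.
#' @return an [NMSVoxelResult-class].
#' @export
selectModel <- function(fits, confidenceLevel = 0.95) {
  stopifnot(length(fits) == 3L)
  ord <- vapply(fits, function(f) f@modelOrder, integer(1))
  if (!identical(ord, 1:3)) stop("fits must be ordered models 1, 2, 3")
  rss <- vapply(fits, function(f) f@rss, numeric(1))
  tss <- fits[[1]]@tss
  tol <- 1e-8 * (tss + rss[1])
  if (rss[2] > rss[1] + tol || rss[3] > rss[2] + tol)
    .contract("rss must be non-increasing in model order")
  lab <- .selectLabels(rss[1], rss[2], rss[3], tss, fits[[1]]@nObs,
                       confidenceLevel)
  new("NMSVoxelResult", label = lab, fits = fits,
      confidenceLevel = confidenceLevel)
}

#' Fit and select for a single voxel trace
#'
#' @inheritParams fitModel3
#' @param confidenceLevel confidence level for the F-tests.
#' @return an [NMSVoxelResult-class].
#' @export
fitVoxel <- function(trace, aif, grid, confidenceLevel = 0.95,
                     kepBounds = c(1e-3, 5), nCoarse = 60L) {
  selectModel(list(fitModel1(trace, aif, grid),
                   fitModel2(trace, aif, grid),
                   fitModel3(trace, aif, grid, kepBounds, nCoarse)),
              confidenceLevel)
}

#' Nested model selection over a masked volume
#'
#' Applies the three nested fits and sequential F-test selection to every
#' voxel inside the brain mask of a 4-D delta-R1 volume, storing all
#' per-model parameter maps needed for model averaging (vp from each model,
#' Ktrans from models 2-3, Kep from model 3, and the three RSS maps).
#'
#' @param x a [SyntheticStudy-class], or a 4-D numeric array (x, y, z, t).
#' @param mask 3-D logical array (taken from the study if omitted; defaults
#'   to all-TRUE for a plain array).
#' @param aif an [AIFCurve-class] (taken from the study if omitted).
#' @param grid a [TimeGrid-class] (taken from the AIF if omitted).
#' @param confidenceLevel confidence level for the F-tests, default 0.95.
#' @param kepBounds,nCoarse Kep search controls, see [fitModel3()].
#' @return an [NMSVolumeResult-class].
#' @examples
#' g <- timeGrid(120, 1.55, 30, 10)
#' a <- makeAIF(g)
#' spec <- phantomSpec(dim = c(8, 8, 1), coreRadius = 2, rimRadius = 3.5,
#'                     noiseSd = 0)
#' st <- simulateStudy(spec, g, a)
#' fitVolume(st)
#' @export
fitVolume <- function(x, mask = NULL, aif = NULL, grid = NULL,
                      confidenceLevel = 0.95, kepBounds = c(1e-3, 5),
                      nCoarse = 60L) {
  if (is(x, "SyntheticStudy")) {
    if (is.null(mask)) mask <- x@mask
    if (is.null(aif)) aif <- x@aif
    vol <- x@dr1
  } else vol <- x
  if (is.null(grid)) {
    if (!is(aif, "AIFCurve")) stop("grid required when aif is a plain vector")
    grid <- acqGrid(aif)
  }
  d <- dim(vol)
  if (length(d) != 4L) stop("volume must be 4-D (x, y, z, t)")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3])) .contract("mask shape mismatch")
  vox <- which(mask)
  if (!length(vox)) .degenerate("empty brain mask")

  flat <- matrix(vol, prod(d[1:3]), d[4])
  Y <- t(flat[vox, retainedIndices(grid), drop = FALSE])
  r <- .fitCore(Y, .aifVals(aif), grid, kepBounds, nCoarse)
  labels <- .selectLabels(r$rss1, r$rss2, r$rss3, r$tss, r$nObs,
                          confidenceLevel)

  blank <- array(NA_real_, d[1:3])
  fill <- function(v) { a <- blank; a[vox] <- v; a }
  labelMap <- array(0L, d[1:3])
  labelMap[vox] <- labels
  new("NMSVolumeResult", labelMap = labelMap,
      maps = list(vpM1 = fill(r$vp1), vpM2 = fill(r$vp2),
                  ktransM2 = fill(r$ktrans2), vpM3 = fill(r$vp3),
                  ktransM3 = fill(r$ktrans3), kepM3 = fill(r$kep3),
                  rss1 = fill(r$rss1), rss2 = fill(r$rss2),
                  rss3 = fill(r$rss3)),
      mask = mask, confidenceLevel = confidenceLevel)
}
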