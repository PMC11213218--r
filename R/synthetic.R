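## Synthetic DCE phantom generator.
##
## The phantom mirrors the statistical structure the analysis assumes: a
## shared population AIF, three concentric tissue classes (normal
## vasculature, leaky tumor core, leaky tumor rim with back-flux) whose
## traces follow the three nested models exactly, per-voxel parameters drawn
## from physiologically plausible uniform ranges, i.i.d. Gaussian noise on
## delta-R1 (a derived relaxivity change, not a magnitude signal, so the
## noise is Gaussian rather than Rician), frame exclusion, and unit-peak
## shape normalization for the SOM.

#' Simulate one phantom DCE study
#'
#' Per voxel, parameters are drawn from the region's distributions, the
#' matching nested model is forward-evaluated for the shared AIF, and
#' Gaussian noise with standard deviation `noiseSd x (phantom peak signal)`
#' is added to every frame. The ground-truth labels and parameter maps are
#' retained.
#'
#' @param spec a [PhantomSpec-class].
#' @param grid a [TimeGrid-class].
#' @param aif an [AIFCurve-class] on `grid`.
#' @param animalId character identifier.
#' @param center optional in-plane tumor center c(x, y) in voxels (defaults
#'   to the slice center).
#' @return a [SyntheticStudy-class].
#' @examples
#' g <- timeGrid(100, 1.55, 30, 10)
#' st <- simulateStudy(phantomSpec(dim = c(8, 8, 1), coreRadius = 2,
#'                                 rimRadius = 3, noiseSd = 0), g, makeAIF(g))
#' st
#' @export
simulateStudy <- function(spec, grid, aif, animalId = "A01", center = NULL) {
  stopifnot(is(spec, "PhantomSpec"), is(grid, "TimeGrid"))
  validObject(spec)
  d <- spec@dim
  nt <- nFrames(grid)
  aifv <- .aifVals(aif)
  if (length(aifv) != nt) .contract("AIF and grid lengths differ")
  if (is.null(center)) center <- (d[1:2] + 1) / 2

  ix <- rep(seq_len(d[1]), times = d[2])
  iy <- rep(seq_len(d[2]), each = d[1])
  rad <- sqrt((ix - center[1])^2 + (iy - center[2])^2)
  sliceLab <- rep(1L, d[1] * d[2])
  sliceLab[rad <= spec@rimRadius] <- 3L
  sliceLab[rad <= spec@coreRadius] <- 2L
  labels <- array(rep(sliceLab, d[3]), d)
  mask <- array(TRUE, d)

  V <- prod(d)
  lab <- as.vector(labels)
  set.seed(spec@seed)
  vp <- stats::runif(V, spec@vpRange[1], spec@vpRange[2])
  kt <- rep(0, V)
  kep <- rep(0, V)
  leaky <- lab >= 2L
  kt[leaky] <- stats::runif(sum(leaky), spec@ktransRange[1],
                            spec@ktransRange[2])
  back <- lab == 3L
  kep[back] <- stats::runif(sum(back), spec@kepRange[1], spec@kepRange[2])

  ci <- cumulativeIntegral(aifv, grid)
  traces <- outer(vp, aifv)                       # V x nt
  traces[leaky, ] <- traces[leaky, , drop = FALSE] +
    outer(kt[leaky] / 60, ci)
  for (j in which(back)) {
    conv <- expConvolution(aifv, kep[j], grid)
    traces[j, ] <- vp[j] * aifv + kt[j] / 60 * conv
  }
  if (spec@noiseSd > 0) {
    peak <- max(abs(traces))
    traces <- traces + stats::rnorm(length(traces), sd = spec@noiseSd * peak)
  }

  mkmap <- function(v, keep) { v[!keep] <- NA_real_; array(v, d) }
  new("SyntheticStudy",
      dr1 = array(traces, c(d, nt)),
      labels = labels,
      truth = list(vp = array(vp, d), ktrans = mkmap(kt, leaky),
                   kep = mkmap(kep, back)),
      aif = if (is(aif, "AIFCurve")) aif else aifCurve(aifv, grid),
      mask = mask, animalId = animalId)
}

#' Exclude initial frames and shape-normalize profiles
#'
#' Drops the excluded initial frames, subtracts the mean of the remaining
#' pre-injection (baseline) frames, and divides by the maximum absolute
#' value (unit-peak shape normalization; `method = "l2"` divides by the
#' Euclidean norm instead). An all-zero trace is returned as all-zero and
#' flagged in the `"excluded"` attribute. Profiles that already carry only
#' the retained frames are normalized in place (the operation is
#' idempotent).
#'
#' @param traces numeric vector or matrix (one profile per row), with either
#'   all grid frames or only the retained frames as columns.
#' @param grid a [TimeGrid-class].
#' @param method "peak" (default) or "l2".
#' @return matrix of normalized profiles (rows = profiles, columns =
#'   retained frames), with a logical `"excluded"` attribute per profile.
#' @export
excludeAndNormalize <- function(traces, grid, method = c("peak", "l2")) {
  method <- match.arg(method)
  X <- if (is.matrix(traces)) traces else matrix(traces, nrow = 1)
  idx <- retainedIndices(grid)
  if (ncol(X) == nFrames(grid)) {
    X <- X[, idx, drop = FALSE]
  } else if (ncol(X) != length(idx)) {
    .contract("profiles must carry all frames or the retained frames")
  }
  nBase <- grid@injectionIndex - grid@firstRetained
  if (nBase > 0) {
    base <- rowMeans(X[, seq_len(nBase), drop = FALSE])
    X <- X - base
  }
  nrm <- switch(method,
    peak = apply(abs(X), 1, max),
    l2 = sqrt(rowSums(X * X)))
  excluded <- nrm == 0
  nrm[excluded] <- 1
  out <- X / nrm
  attr(out, "excluded") <- excluded
  out
}

#' Generate a multi-animal phantom cohort
#'
#' Each animal gets its own parameter draws and a jittered tumor center
#' (uniform within +/- 2 voxels in-plane), with per-animal seeds derived
#' deterministically from the cohort seed.
#'
#' @param nAnimals number of studies to generate.
#' @param spec template [PhantomSpec-class].
#' @param grid shared [TimeGrid-class].
#' @param aif shared [AIFCurve-class].
#' @param seed cohort seed (defaults to the spec seed).
#' @return list of [SyntheticStudy-class] objects.
#' @export
makeCohort <- function(nAnimals, spec, grid, aif, seed = spec@seed) {
  lapply(seq_len(nAnimals), function(i) {
    si <- deriveSeed(seed, paste0("animal", i))
    set.seed(si)
    center <- (spec@dim[1:2] + 1) / 2 + stats::runif(2, -2, 2)
    sp <- spec
    sp@seed <- deriveSeed(si, "study")
    simulateStudy(sp, grid, aif, animalId = sprintf("A%02d", i),
                  center = center)
  })
}
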