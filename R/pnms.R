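## Probabilistic nested model selection (PNMS).
##
## The labeled hit map of a trained SOM yields, per neuron, the fraction of
## training profiles of each nested model that the neuron attracts; a voxel
## inherits the probabilities of its BMU. Thresholding the probability maps
## gives the model regions (Model-1 mask first, Models 2/3 in the
## remainder), and the permeability parameters are probability-weighted
## averages of the per-model NMS fits:
##
##   vp     = (P1 vp_M1 + P2 vp_M2 + P3 vp_M3) / (P1 + P2 + P3)
##   Ktrans = (P2 Kt_M2 + P3 Kt_M3) / (P2 + P3)
##   ve     = Ktrans / Kep_M3

#' Per-neuron model probabilities from a labeled hit map
#'
#' For hit-bearing neurons, Pm = hits_m / total hits. Empty neurons
#' (interpolating units) borrow the probabilities of the nearest hit-bearing
#' neuron in lattice distance, ties to the lowest index; their provenance
#' records the donor.
#'
#' @param hitmap a [HitMap-class].
#' @param grid a [SOMGrid-class] (or [SOMModel-class]).
#' @return a [NeuronProbabilityTable-class].
#' @export
neuronProbabilities <- function(hitmap, grid) {
  if (is(grid, "SOMModel")) grid <- grid@grid
  total <- hitmap@total
  if (all(total == 0L)) .degenerate("all neurons are empty")
  n <- length(total)
  probs <- matrix(0, n, 3)
  hit <- total > 0L
  probs[hit, ] <- hitmap@counts[hit, , drop = FALSE] / total[hit]
  provenance <- integer(n)
  if (any(!hit)) {
    D <- grid@distances
    donors <- which(hit)
    for (i in which(!hit)) {
      d <- D[i, donors]
      donor <- donors[which.min(d)]   # which.min takes the first = lowest index
      probs[i, ] <- probs[donor, ]
      provenance[i] <- donor
    }
  }
  new("NeuronProbabilityTable", probs = probs, nHits = total,
      provenance = provenance)
}

## normalized profiles for the masked voxels of a study, one per row
.studyProfiles <- function(study, mask = study@mask) {
  d <- dim(study@dr1)
  flat <- matrix(study@dr1, prod(d[1:3]), d[4])
  excludeAndNormalize(flat[which(mask), , drop = FALSE], acqGrid(study))
}

#' Voxel-wise model probability volume
#'
#' Each masked voxel's normalized profile is mapped to its BMU and inherits
#' that neuron's (P1, P2, P3). Region masks are thresholded at `tau`:
#' the Model-1 region is taken first and the Model-2/3 regions are assigned
#' within the remainder (at tau = 0.5 the three are disjoint by
#' construction). Voxels with all probabilities below `tau` belong to no
#' region.
#'
#' @param x a [SyntheticStudy-class], or a numeric matrix of *normalized*
#'   profiles (one per masked voxel, in `which(mask)` order).
#' @param model a trained [SOMModel-class].
#' @param table a [NeuronProbabilityTable-class].
#' @param mask 3-D logical array (required when `x` is a matrix; taken from
#'   the study otherwise).
#' @param tau region threshold in (0, 1], default 0.5.
#' @return a [ProbabilityVolume-class].
#' @export
voxelProbabilities <- function(x, model, table, mask = NULL, tau = 0.5) {
  if (is(x, "SyntheticStudy")) {
    if (is.null(mask)) mask <- x@mask
    profiles <- .studyProfiles(x, mask)
  } else {
    if (is.null(mask)) stop("mask is required with a profile matrix")
    profiles <- as.matrix(x)
  }
  if (nrow(profiles) != sum(mask)) .contract("profile count != masked voxels")
  if (max(abs(profiles)) > 1 + 1e-6)
    .contract("profiles do not look normalized (|value| > 1)")
  bmu <- findBMU(model, profiles)
  P <- table@probs[bmu, , drop = FALSE]
  d <- dim(mask)
  probs <- array(NA_real_, c(d, 3L))
  vox <- which(mask)
  for (m in 1:3) {
    pm <- array(NA_real_, d)
    pm[vox] <- P[, m]
    probs[, , , m] <- pm
  }
  finite0 <- function(a) { a[!is.finite(a)] <- 0; array(a, d) }
  p1 <- finite0(probs[, , , 1])
  p2 <- finite0(probs[, , , 2])
  p3 <- finite0(probs[, , , 3])
  m1 <- p1 > tau & mask
  m2 <- p2 > tau & mask & !m1
  m3 <- p3 > tau & mask & !m1 & !m2
  new("ProbabilityVolume", probs = probs, mask = mask, tau = tau,
      regions = list(m1, m2, m3))
}

#' Probability-weighted plasma volume
#'
#' Weighted mean of the three per-model vp estimates with the model
#' probabilities as weights. Where the weight total is zero the value is
#' undefined (NA).
#'
#' @param p1,p2,p3 model probabilities (vectors or arrays).
#' @param vpM1,vpM2,vpM3 per-model vp estimates (same shape).
#' @return weighted vp, same shape as the inputs.
#' @export
averagedVp <- function(p1, p2, p3, vpM1, vpM2, vpM3) {
  den <- p1 + p2 + p3
  out <- (p1 * vpM1 + p2 * vpM2 + p3 * vpM3) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Probability-weighted forward transfer constant
#'
#' Weighted mean of the Model-2 and Model-3 Ktrans estimates. Where
#' P2 + P3 = 0 the voxel is non-leaky and Ktrans is defined as 0.
#'
#' @param p2,p3 model probabilities.
#' @param ktransM2,ktransM3 per-model Ktrans estimates (1/min).
#' @return weighted Ktrans, same shape as the inputs.
#' @export
averagedKtrans <- function(p2, p3, ktransM2, ktransM3) {
  if (any(c(p2, p3, ktransM2, ktransM3) < 0, na.rm = TRUE))
    stop("probabilities and Ktrans estimates must be non-negative")
  den <- p2 + p3
  num <- p2 * ktransM2 + p3 * ktransM3
  out <- ifelse(!is.na(den) & den == 0, 0, num / den)
  out
}

#' Interstitial volume fraction from averaged Ktrans
#'
#' ve = Ktrans / Kep(M3). Where Kep(M3) is below `kepFloor` the ratio is
#' numerically meaningless and ve is undefined (NA); where the averaged
#' Ktrans is 0, ve is 0.
#'
#' @param ktransAvg averaged Ktrans (1/min).
#' @param kepM3 Model-3 Kep estimates (1/min).
#' @param kepFloor smallest usable Kep (default 1e-3 1/min).
#' @return ve (fraction), same shape as the inputs.
#' @export
averagedVe <- function(ktransAvg, kepM3, kepFloor = 1e-3) {
  out <- ktransAvg / kepM3
  out[!is.na(kepM3) & kepM3 < kepFloor] <- NA_real_
  out[!is.na(ktransAvg) & ktransAvg == 0 & !is.na(kepM3) &
        kepM3 >= kepFloor] <- 0
  out
}

#' Model-averaged permeability maps
#'
#' Applies the probability-weighted averaging to the per-model parameter
#' maps of an NMS result. vp and ve are reported in percent, Ktrans in
#' 1/min.
#'
#' @param nmsResult an [NMSVolumeResult-class].
#' @param probVolume a [ProbabilityVolume-class] on the same lattice.
#' @param kepFloor smallest usable Kep for ve (1/min).
#' @return an [AveragedParameterMaps-class].
#' @export
pnmsParameterMaps <- function(nmsResult, probVolume, kepFloor = 1e-3) {
  if (!identical(dim(nmsResult@labelMap), dim(probVolume@mask)))
    .contract("NMS result and probability volume dimensions differ")
  d <- dim(probVolume@mask)
  p1 <- array(probVolume@probs[, , , 1], d)
  p2 <- array(probVolume@probs[, , , 2], d)
  p3 <- array(probVolume@probs[, , , 3], d)
  m <- nmsResult@maps
  vp <- 100 * averagedVp(p1, p2, p3, m$vpM1, m$vpM2, m$vpM3)
  kt <- averagedKtrans(p2, p3, m$ktransM2, m$ktransM3)
  ve <- 100 * averagedVe(kt, m$kepM3, kepFloor)
  new("AveragedParameterMaps", vp = vp, ktrans = kt, ve = ve,
      kepFloor = kepFloor)
}

#' Parameter maps of the NMS-selected models
#'
#' The conventional counterpart of [pnmsParameterMaps()]: per voxel, vp from
#' the selected model, Ktrans from the selected model when it is 2 or 3
#' (0 for Model-1 voxels), and ve = Ktrans(M3)/Kep(M3) for Model-3 voxels
#' (NA elsewhere). vp and ve in percent, Ktrans in 1/min.
#'
#' @param nmsResult an [NMSVolumeResult-class].
#' @param kepFloor smallest usable Kep for ve (1/min).
#' @return an [AveragedParameterMaps-class].
#' @export
nmsSelectedMaps <- function(nmsResult, kepFloor = 1e-3) {
  lab <- nmsResult@labelMap
  m <- nmsResult@maps
  vp <- array(NA_real_, dim(lab))
  vp[lab == 1L] <- m$vpM1[lab == 1L]
  vp[lab == 2L] <- m$vpM2[lab == 2L]
  vp[lab == 3L] <- m$vpM3[lab == 3L]
  kt <- array(NA_real_, dim(lab))
  kt[lab == 1L] <- 0
  kt[lab == 2L] <- m$ktransM2[lab == 2L]
  kt[lab == 3L] <- m$ktransM3[lab == 3L]
  ve <- array(NA_real_, dim(lab))
  i3 <- lab == 3L & !is.na(m$kepM3) & m$kepM3 >= kepFloor
  ve[i3] <- m$ktransM3[i3] / m$kepM3[i3]
  new("AveragedParameterMaps", vp = 100 * vp, ktrans = kt, ve = 100 * ve,
      kepFloor = kepFloor)
}
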