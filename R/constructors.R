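#' Build a uniform acquisition time grid
#'
#' Defaults follow a 400-frame dynamic acquisition at 1.55 s per frame with
#' the contrast bolus arriving about 60 s after the start, and the first 20
#' frames (about 30 s) excluded from analysis.
#'
#' @param nFrames number of frames (default 400).
#' @param spacing frame spacing in seconds (default 1.55).
#' @param injectionTime bolus arrival time in seconds (default 60); the first
#'   frame at or after this time is the injection frame.
#' @param excludeFrames number of initial frames excluded from analysis
#'   (default 20).
#' @return a [TimeGrid-class].
#' @examples
#' g <- timeGrid()
#' nFrames(g)
#' injectionIndex(g)
#' @export
timeGrid <- function(nFrames = 400L, spacing = 1.55, injectionTime = 60,
                     excludeFrames = 20L) {
  nFrames <- as.integer(nFrames)
  tp <- (seq_len(nFrames) - 1) * spacing
  ii <- which(tp >= injectionTime)[1]
  if (is.na(ii)) stop("injectionTime lies beyond the acquisition window")
  new("TimeGrid", timepoints = tp, injectionIndex = as.integer(ii),
      firstRetained = as.integer(excludeFrames + 1L))
}

#' Wrap AIF values sampled on a grid
#'
#' @param values numeric vector of relaxivity-change values (1/s), one per
#'   frame.
#' @param grid a [TimeGrid-class].
#' @return an [AIFCurve-class].
#' @export
aifCurve <- function(values, grid) {
  new("AIFCurve", values = as.numeric(values), grid = grid)
}

#' Construct pharmacokinetic parameters
#'
#' @param vp plasma volume fraction (dimensionless).
#' @param ktrans forward transfer constant (1/min).
#' @param kep reverse transfer constant (1/min).
#' @param modelOrder 1, 2 or 3.
#' @return a [PKParams-class].
#' @export
pkParams <- function(vp = 0, ktrans = 0, kep = 0, modelOrder = 3L) {
  new("PKParams", vp = as.numeric(vp), ktrans = as.numeric(ktrans),
      kep = as.numeric(kep), modelOrder = as.integer(modelOrder))
}

#' Configure a self-organizing map
#'
#' Defaults match the study configuration: an 8x8 hexagonal lattice, initial
#' neighborhood radius 3, 100 ordering-phase epochs ("cover steps"), and at
#' most 250 batch-training epochs.
#'
#' @param rows,cols lattice dimensions.
#' @param layout lattice layout; only "hexagonal" is implemented.
#' @param initialRadius initial neighborhood radius.
#' @param orderingSteps ordering-phase epoch count.
#' @param maxEpochs maximum number of batch epochs.
#' @param init "linear" (deterministic principal-plane initialization) or
#'   "random" (seeded sample of input profiles).
#' @param seed integer seed (used by random initialization only).
#' @return a [SOMConfig-class].
#' @examples
#' cfg <- somConfig()
#' cfg
#' @export
somConfig <- function(rows = 8L, cols = 8L, layout = "hexagonal",
                      initialRadius = 3, orderingSteps = 100L,
                      maxEpochs = 250L, init = "linear", seed = 1L) {
  new("SOMConfig", rows = as.integer(rows), cols = as.integer(cols),
      layout = layout, initialRadius = as.numeric(initialRadius),
      orderingSteps = as.integer(orderingSteps),
      maxEpochs = as.integer(maxEpochs), init = init, seed = as.integer(seed))
}

#' Specify a synthetic DCE phantom
#'
#' @param dim spatial dimensions, default c(32, 32, 3).
#' @param coreRadius radius (voxels) of the Model-2 tumor core disc.
#' @param rimRadius outer radius of the Model-3 rim annulus.
#' @param vpRange uniform range for vp (fraction).
#' @param ktransRange uniform range for Ktrans (1/min), models 2-3.
#' @param kepRange uniform range for Kep (1/min), model 3.
#' @param noiseSd Gaussian noise SD relative to the phantom's peak signal
#'   (0.05 corresponds to SNR 20 at the peak).
#' @param seed integer seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(32L, 32L, 3L), coreRadius = 5,
                        rimRadius = 8, vpRange = c(0.01, 0.04),
                        ktransRange = c(0.05, 0.3), kepRange = c(0.5, 2.5),
                        noiseSd = 0.05, seed = 1L) {
  new("PhantomSpec", dim = as.integer(dim), coreRadius = coreRadius,
      rimRadius = rimRadius, vpRange = vpRange, ktransRange = ktransRange,
      kepRange = kepRange, noiseSd = noiseSd, seed = as.integer(seed))
}
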