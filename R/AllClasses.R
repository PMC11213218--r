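#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Acquisition time grid
#'
#' A uniformly spaced acquisition grid for a dynamic contrast-enhanced (DCE)
#' MRI study. Times are in seconds. `injectionIndex` is the (1-based) index of
#' the first frame at or after bolus arrival; frames before it are
#' pre-injection baseline. `firstRetained` is the first frame kept for
#' analysis: the initial frames of a heavily saturated dynamic acquisition are
#' discarded so the spin system can settle, and all fitting and normalization
#' operate on frames `firstRetained ... nFrames`.
#'
#' @slot timepoints numeric vector of frame times (seconds), uniformly spaced.
#' @slot injectionIndex integer, first post-injection frame (1-based).
#' @slot firstRetained integer, first frame retained for analysis (1-based).
#' @export
setClass("TimeGrid",
  representation(
    timepoints = "numeric",
    injectionIndex = "integer",
    firstRetained = "integer"
  )
)

setValidity("TimeGrid", function(object) {
  tp <- object@timepoints
  if (length(tp) < 3L) return("need at least 3 timepoints")
  if (any(!is.finite(tp))) return("timepoints must be finite")
  d <- diff(tp)
  if (any(d <= 0)) return("timepoints must be strictly increasing")
  if (max(d) - min(d) > 1e-9 * max(abs(d)))
    return("timepoints must be uniformly spaced (1e-9 relative)")
  ii <- object@injectionIndex
  fr <- object@firstRetained
  if (length(ii) != 1L || length(fr) != 1L)
    return("injectionIndex and firstRetained must be scalars")
  if (!(fr >= 1L && fr <= ii && ii <= length(tp)))
    return("need 1 <= firstRetained <= injectionIndex <= nFrames")
  TRUE
})

#' Arterial input function sampled on a TimeGrid
#'
#' Contrast-agent concentration in plasma, expressed as a longitudinal
#' relaxivity change (1/s), sampled at each frame of its [TimeGrid-class].
#' The curve is zero (to within a small noise floor) before the injection
#' frame.
#'
#' @slot values numeric vector, one value per grid frame (1/s).
#' @slot grid a [TimeGrid-class].
#' @export
setClass("AIFCurve",
  representation(values = "numeric", grid = "TimeGrid")
)

setValidity("AIFCurve", function(object) {
  v <- object@values
  g <- object@grid
  if (length(v) != length(g@timepoints))
    return("AIF length must match its TimeGrid")
  if (any(!is.finite(v))) return("AIF values must be finite")
  pk <- max(abs(v))
  if (pk > 0) {
    pre <- v[seq_len(g@injectionIndex - 1L)]
    if (length(pre) && max(abs(pre)) > 0.05 * pk)
      return("AIF must be (near) zero before the injection frame")
  }
  TRUE
})

#' Pharmacokinetic parameters of one nested model
#'
#' Parameters of the nested Patlak-family models: `vp` (plasma volume
#' fraction, dimensionless), `ktrans` (forward volumetric transfer constant,
#' 1/min), `kep` (reverse transfer constant, 1/min). `modelOrder` selects the
#' model: 1 = vascular only (vp), 2 = leakage without back-flux (vp, Ktrans),
#' 3 = leakage with back-flux (vp, Ktrans, Kep). The interstitial volume
#' fraction ve = Ktrans/Kep is derived, defined only when kep > 0.
#'
#' @slot vp numeric scalar >= 0.
#' @slot ktrans numeric scalar >= 0 (1/min); unused for model 1.
#' @slot kep numeric scalar >= 0 (1/min); unused for models 1-2.
#' @slot modelOrder integer 1, 2 or 3.
#' @export
setClass("PKParams",
  representation(vp = "numeric", ktrans = "numeric", kep = "numeric",
                 modelOrder = "integer")
)

setValidity("PKParams", function(object) {
  if (!object@modelOrder %in% 1:3) return("modelOrder must be 1, 2 or 3")
  if (object@vp < 0 || object@ktrans < 0 || object@kep < 0)
    return("vp, ktrans and kep must be non-negative")
  TRUE
})

#' Least-squares fit of one nested model to one voxel trace
#'
#' `rss` is the residual sum of squares of the *unconstrained* nested
#' least-squares fit: this is the quantity the sequential partial F-tests
#' compare, and it is non-increasing in model order by construction. The
#' reported `params` are the non-negativity-constrained estimates
#' (clip-and-refit), which are what the parameter maps carry. `tss` is the
#' total sum of squares of the retained trace, used as the scale for the
#' numerical significance floor in model selection.
#'
#' @slot modelOrder integer 1, 2 or 3.
#' @slot params a [PKParams-class] (constrained estimates).
#' @slot rss unconstrained residual sum of squares.
#' @slot tss total sum of squares of the retained trace.
#' @slot nFree number of fitted parameters (1, 2 or 3).
#' @slot nObs number of retained frames used.
#' @export
setClass("ModelFit",
  representation(modelOrder = "integer", params = "PKParams",
                 rss = "numeric", tss = "numeric",
                 nFree = "integer", nObs = "integer")
)

setValidity("ModelFit", function(object) {
  if (object@rss < 0) return("rss must be non-negative")
  if (!object@nFree %in% 1:3) return("nFree must be 1, 2 or 3")
  if (object@nObs <= object@nFree) return("need nObs > nFree")
  TRUE
})

#' Per-voxel nested model selection result
#'
#' The label is the highest model order whose additional parameter was
#' statistically significant in the sequential partial F-tests at the stated
#' confidence level. All three fits are retained regardless of the label,
#' because model averaging needs vp from all models, Ktrans from models 2-3
#' and Kep from model 3.
#'
#' @slot label integer 1, 2 or 3.
#' @slot fits list of the three [ModelFit-class] objects (orders 1, 2, 3).
#' @slot confidenceLevel numeric in (0, 1).
#' @export
setClass("NMSVoxelResult",
  representation(label = "integer", fits = "list", confidenceLevel = "numeric")
)

setValidity("NMSVoxelResult", function(object) {
  if (!object@label %in% 1:3) return("label must be 1, 2 or 3")
  if (length(object@fits) != 3L) return("need exactly three fits")
  TRUE
})

#' Volume-level nested model selection result
#'
#' Per-voxel model labels plus every per-model parameter map the
#' model-averaging stage consumes: vp from each model, Ktrans from models 2
#' and 3, Kep from model 3, and the three unconstrained RSS maps. Maps are NA
#' outside the brain mask; the label map is 0 there.
#'
#' @slot labelMap 3-D integer array (0 outside mask).
#' @slot maps named list of 3-D numeric arrays: vpM1, vpM2, ktransM2, vpM3,
#'   ktransM3, kepM3, rss1, rss2, rss3.
#' @slot mask 3-D logical array.
#' @slot confidenceLevel numeric.
#' @export
setClass("NMSVolumeResult",
  representation(labelMap = "array", maps = "list", mask = "array",
                 confidenceLevel = "numeric")
)

setValidity("NMSVolumeResult", function(object) {
  need <- c("vpM1", "vpM2", "ktransM2", "vpM3", "ktransM3", "kepM3",
            "rss1", "rss2", "rss3")
  if (!all(need %in% names(object@maps)))
    return(paste("maps must contain:", paste(need, collapse = ", ")))
  if (!identical(dim(object@labelMap), dim(object@mask)))
    return("labelMap and mask dimensions differ")
  lab <- object@labelMap[object@mask]
  if (length(lab) && !all(lab %in% 1:3))
    return("labels inside the mask must be 1, 2 or 3")
  for (nm in c("vpM1", "vpM2", "ktransM2", "vpM3", "ktransM3", "kepM3")) {
    v <- object@maps[[nm]][object@mask]
    if (any(is.finite(v) & v < 0)) return(paste(nm, "has negative values"))
  }
  TRUE
})

#' Self-organizing map configuration
#'
#' Hyperparameters of the batch-trained Kohonen SOM: an 8x8 hexagonal
#' topology, an initial neighborhood radius of 3 that decays linearly to 1
#' over the `orderingSteps` ordering-phase epochs (the "cover steps") and is
#' then held at 1 for the remaining tuning epochs, up to `maxEpochs` batch
#' epochs in total.
#'
#' @slot rows,cols integer grid dimensions (default 8x8).
#' @slot layout character, currently "hexagonal".
#' @slot initialRadius numeric initial neighborhood radius (default 3).
#' @slot orderingSteps integer ordering-phase epoch count (default 100).
#' @slot maxEpochs integer maximum batch epochs (default 250).
#' @slot init character, "linear" (deterministic, principal-plane) or
#'   "random" (seeded sample of input profiles).
#' @slot seed integer seed, used only by random initialization.
#' @export
setClass("SOMConfig",
  representation(rows = "integer", cols = "integer", layout = "character",
                 initialRadius = "numeric", orderingSteps = "integer",
                 maxEpochs = "integer", init = "character", seed = "integer")
)

setValidity("SOMConfig", function(object) {
  if (object@rows * object@cols < 2L) return("need at least 2 neurons")
  if (object@initialRadius < 1) return("initialRadius must be >= 1")
  if (object@orderingSteps > object@maxEpochs)
    return("orderingSteps must be <= maxEpochs")
  if (object@orderingSteps < 1L || object@maxEpochs < 1L)
    return("epoch counts must be positive")
  if (!object@layout %in% "hexagonal") return("layout must be 'hexagonal'")
  if (!object@init %in% c("linear", "random"))
    return("init must be 'linear' or 'random'")
  TRUE
})

#' SOM lattice geometry
#'
#' Hexagonally packed neuron coordinates (offset rows) and the matrix of
#' pairwise Euclidean distances in lattice space. Interior nearest neighbors
#' are at distance 1.
#'
#' @slot coords numeric matrix (neurons x 2) of lattice positions.
#' @slot distances numeric matrix (neurons x neurons).
#' @export
setClass("SOMGrid",
  representation(coords = "matrix", distances = "matrix")
)

setValidity("SOMGrid", function(object) {
  d <- object@distances
  if (nrow(d) != ncol(d)) return("distance matrix must be square")
  if (nrow(object@coords) != nrow(d))
    return("coords and distances disagree on neuron count")
  if (max(abs(d - t(d))) > 1e-12) return("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-12) return("distance diagonal must be zero")
  TRUE
})

#' Trained self-organizing map
#'
#' @slot config the [SOMConfig-class] used for training.
#' @slot grid the [SOMGrid-class] lattice.
#' @slot weights numeric matrix (neurons x input dimension) of prototypes.
#' @slot epochsTrained integer, epochs actually run.
#' @slot converged logical, TRUE if BMU assignments stabilized before
#'   `maxEpochs`.
#' @export
setClass("SOMModel",
  representation(config = "SOMConfig", grid = "SOMGrid", weights = "matrix",
                 epochsTrained = "integer", converged = "logical")
)

setValidity("SOMModel", function(object) {
  n <- object@config@rows * object@config@cols
  if (nrow(object@weights) != n)
    return("weights must have one row per neuron")
  if (any(!is.finite(object@weights))) return("weights must be finite")
  TRUE
})

#' BMU hit map with per-label counts
#'
#' Per-neuron counts of input profiles whose best matching unit is that
#' neuron, overall and split by nested-model label (1/2/3).
#'
#' @slot counts integer matrix (neurons x 3), per-label hits.
#' @slot total integer vector, total hits per neuron.
#' @export
setClass("HitMap",
  representation(counts = "matrix", total = "integer")
)

setValidity("HitMap", function(object) {
  if (ncol(object@counts) != 3L) return("counts must have 3 label columns")
  if (nrow(object@counts) != length(object@total))
    return("counts and total disagree on neuron count")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (any(rowSums(object@counts) != object@total))
    return("per-label counts must sum to the neuron total")
  TRUE
})

#' Per-neuron nested-model probabilities
#'
#' For each neuron, the fraction of its training hits carrying each
#' nested-model label. Neurons with no hits borrow the probabilities of the
#' nearest hit-bearing neuron in lattice distance (tie-break: lowest index);
#' `provenance` is 0 for direct estimates and the donor index for borrowed
#' ones.
#'
#' @slot probs numeric matrix (neurons x 3), rows sum to 1.
#' @slot nHits integer vector of per-neuron hit counts.
#' @slot provenance integer vector (0 = direct, j > 0 = borrowed from j).
#' @export
setClass("NeuronProbabilityTable",
  representation(probs = "matrix", nHits = "integer", provenance = "integer")
)

setValidity("NeuronProbabilityTable", function(object) {
  p <- object@probs
  if (ncol(p) != 3L) return("probs must have 3 columns")
  if (any(p < -1e-12 | p > 1 + 1e-12)) return("probabilities must lie in [0,1]")
  if (max(abs(rowSums(p) - 1)) > 1e-9) return("rows of probs must sum to 1")
  TRUE
})

#' Voxel-wise nested-model probability volume
#'
#' Per-voxel probabilities (P1, P2, P3) of the three nested models, summing
#' to 1 inside the brain mask, plus the thresholded region masks. The Model-1
#' mask is taken first and Models 2/3 are assigned within the remainder; at
#' the default threshold 0.5 the three masks are pairwise disjoint. A voxel
#' whose probabilities are all below the threshold belongs to no region.
#'
#' @slot probs 4-D numeric array (x, y, z, 3).
#' @slot mask 3-D logical brain mask.
#' @slot tau numeric threshold in (0, 1].
#' @slot regions list of three 3-D logical arrays (model regions).
#' @export
setClass("ProbabilityVolume",
  representation(probs = "array", mask = "array", tau = "numeric",
                 regions = "list")
)

setValidity("ProbabilityVolume", function(object) {
  d <- dim(object@probs)
  if (length(d) != 4L || d[4] != 3L) return("probs must be (x, y, z, 3)")
  if (!identical(d[1:3], dim(object@mask))) return("mask dimensions differ")
  if (object@tau <= 0 || object@tau > 1) return("tau must be in (0, 1]")
  s <- object@probs[, , , 1] + object@probs[, , , 2] + object@probs[, , , 3]
  if (any(abs(s[object@mask] - 1) > 1e-9))
    return("P1+P2+P3 must equal 1 inside the mask")
  if (length(object@regions) != 3L) return("need 3 region masks")
  TRUE
})

#' Model-averaged permeability parameter maps
#'
#' Probability-weighted permeability maps: plasma volume vp (percent),
#' forward transfer constant Ktrans (1/min) and interstitial volume fraction
#' ve (percent). ve is NA where the Model-3 reverse constant is below the
#' numerical floor, and vp is NA where the probability denominator vanishes.
#'
#' @slot vp 3-D numeric array, percent.
#' @slot ktrans 3-D numeric array, 1/min.
#' @slot ve 3-D numeric array, percent.
#' @slot kepFloor numeric, kep floor (1/min) below which ve is undefined.
#' @export
setClass("AveragedParameterMaps",
  representation(vp = "array", ktrans = "array", ve = "array",
                 kepFloor = "numeric")
)

#' Synthetic phantom specification
#'
#' Geometry and parameter distributions of the digital DCE phantom: a
#' background of normal vasculature (Model 1), a concentric tumor core with
#' unidirectional leakage (Model 2) and a tumor rim with leakage and
#' back-flux (Model 3), per slice. Parameters are drawn per voxel from
#' uniform distributions over physiologically plausible ranges; i.i.d.
#' Gaussian noise with standard deviation `noiseSd` times the phantom's peak
#' signal is added to every frame.
#'
#' @slot dim integer(3) spatial dimensions (default 32 x 32 x 3).
#' @slot coreRadius,rimRadius numeric disc radii in voxels (core = Model 2,
#'   annulus core..rim = Model 3).
#' @slot vpRange numeric(2), uniform range for vp (fraction).
#' @slot ktransRange numeric(2), uniform range for Ktrans (1/min).
#' @slot kepRange numeric(2), uniform range for Kep (1/min).
#' @slot noiseSd numeric, noise SD relative to the peak signal.
#' @slot seed integer seed.
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", coreRadius = "numeric",
                 rimRadius = "numeric", vpRange = "numeric",
                 ktransRange = "numeric", kepRange = "numeric",
                 noiseSd = "numeric", seed = "integer")
)

setValidity("PhantomSpec", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("dim must be three positive integers")
  if (object@coreRadius <= 0 || object@rimRadius <= object@coreRadius)
    return("need 0 < coreRadius < rimRadius")
  rng <- function(r) length(r) == 2L && r[1] >= 0 && r[2] >= r[1]
  if (!rng(object@vpRange) || !rng(object@ktransRange) ||
      !rng(object@kepRange))
    return("parameter ranges must be non-negative and ordered")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Synthetic DCE study
#'
#' One phantom "animal": a 4-D delta-R1 volume, the ground-truth label and
#' parameter maps it was generated from, the shared arterial input function
#' and time grid, and the brain mask.
#'
#' @slot dr1 4-D numeric array (x, y, z, t).
#' @slot labels 3-D integer array of true model labels.
#' @slot truth named list of 3-D arrays: vp, ktrans, kep (NA where the true
#'   model has no such parameter).
#' @slot aif the [AIFCurve-class] shared by all voxels.
#' @slot mask 3-D logical brain mask.
#' @slot animalId character identifier.
#' @export
setClass("SyntheticStudy",
  representation(dr1 = "array", labels = "array", truth = "list",
                 aif = "AIFCurve", mask = "array", animalId = "character")
)

setValidity("SyntheticStudy", function(object) {
  d <- dim(object@dr1)
  if (length(d) != 4L) return("dr1 must be 4-D (x, y, z, t)")
  if (!identical(d[1:3], dim(object@labels)))
    return("labels dimensions differ from dr1")
  if (d[4] != length(object@aif@values))
    return("time axis must match the AIF grid")
  TRUE
})

#' Nested cross-validation evaluation report
#'
#' Per-fold and pooled agreement between probabilistic and conventional
#' nested model selection: Dice similarity of the Model-2 and Model-3
#' regions, mean permeability parameters under both techniques, mean percent
#' differences, and bootstrap confidence intervals across folds.
#'
#' @slot perFold data.frame with one row per fold.
#' @slot summary named list of pooled means and CI bounds.
#' @slot k integer number of folds.
#' @export
setClass("EvaluationReport",
  representation(perFold = "data.frame", summary = "list", k = "integer")
)
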