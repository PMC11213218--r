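#' @include AllClasses.R
NULL

#' Accessors for pnmsDCE objects
#'
#' Small generics exposing the slots of the core classes: frame counts and
#' indices of a [TimeGrid-class], AIF values, SOM weights and lattice
#' geometry, hit counts, model labels and parameter maps.
#'
#' @param x an object.
#' @param ... unused.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "TimeGrid", function(x) length(x@timepoints))
#' @rdname accessors
#' @export
setMethod("nFrames", "AIFCurve", function(x) length(x@values))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setMethod("timePoints", "TimeGrid", function(x) x@timepoints)
#' @rdname accessors
#' @export
setMethod("timePoints", "AIFCurve", function(x) x@grid@timepoints)

#' @rdname accessors
#' @export
setGeneric("frameSpacing", function(x) standardGeneric("frameSpacing"))
#' @rdname accessors
#' @export
setMethod("frameSpacing", "TimeGrid", function(x) x@timepoints[2] - x@timepoints[1])

#' @rdname accessors
#' @export
setGeneric("injectionIndex", function(x) standardGeneric("injectionIndex"))
#' @rdname accessors
#' @export
setMethod("injectionIndex", "TimeGrid", function(x) x@injectionIndex)

#' @rdname accessors
#' @export
setGeneric("firstRetained", function(x) standardGeneric("firstRetained"))
#' @rdname accessors
#' @export
setMethod("firstRetained", "TimeGrid", function(x) x@firstRetained)

#' Indices of the frames retained for analysis
#' @param grid a [TimeGrid-class].
#' @return integer vector of retained frame indices.
#' @export
retainedIndices <- function(grid) {
  seq.int(grid@firstRetained, nFrames(grid))
}

#' @rdname accessors
#' @export
setGeneric("aifValues", function(x) standardGeneric("aifValues"))
#' @rdname accessors
#' @export
setMethod("aifValues", "AIFCurve", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("acqGrid", function(x) standardGeneric("acqGrid"))
#' @rdname accessors
#' @export
setMethod("acqGrid", "AIFCurve", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("acqGrid", "SyntheticStudy", function(x) x@aif@grid)

#' @rdname accessors
#' @export
setGeneric("somWeights", function(x) standardGeneric("somWeights"))
#' @rdname accessors
#' @export
setMethod("somWeights", "SOMModel", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("gridCoords", function(x) standardGeneric("gridCoords"))
#' @rdname accessors
#' @export
setMethod("gridCoords", "SOMGrid", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("gridCoords", "SOMModel", function(x) x@grid@coords)

#' @rdname accessors
#' @export
setGeneric("gridDistances", function(x) standardGeneric("gridDistances"))
#' @rdname accessors
#' @export
setMethod("gridDistances", "SOMGrid", function(x) x@distances)
#' @rdname accessors
#' @export
setMethod("gridDistances", "SOMModel", function(x) x@grid@distances)

#' @rdname accessors
#' @export
setGeneric("hitCounts", function(x) standardGeneric("hitCounts"))
#' @rdname accessors
#' @export
setMethod("hitCounts", "HitMap", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("totalHits", function(x) standardGeneric("totalHits"))
#' @rdname accessors
#' @export
setMethod("totalHits", "HitMap", function(x) x@total)

#' @rdname accessors
#' @export
setGeneric("neuronProbs", function(x) standardGeneric("neuronProbs"))
#' @rdname accessors
#' @export
setMethod("neuronProbs", "NeuronProbabilityTable", function(x) x@probs)

#' @rdname accessors
#' @export
setGeneric("modelLabels", function(x) standardGeneric("modelLabels"))
#' @rdname accessors
#' @export
setMethod("modelLabels", "NMSVolumeResult", function(x) x@labelMap)
#' @rdname accessors
#' @export
setMethod("modelLabels", "SyntheticStudy", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setMethod("brainMask", "NMSVolumeResult", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("brainMask", "SyntheticStudy", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("brainMask", "ProbabilityVolume", function(x) x@mask)

#' Extract a per-model parameter map
#' @param x an [NMSVolumeResult-class].
#' @param name one of "vpM1", "vpM2", "ktransM2", "vpM3", "ktransM3",
#'   "kepM3", "rss1", "rss2", "rss3".
#' @return a 3-D numeric array (NA outside the mask).
#' @export
paramMap <- function(x, name) {
  stopifnot(is(x, "NMSVolumeResult"))
  if (!name %in% names(x@maps)) stop("unknown map: ", name)
  x@maps[[name]]
}

#' @rdname accessors
#' @export
setGeneric("probMaps", function(x) standardGeneric("probMaps"))
#' @rdname accessors
#' @export
setMethod("probMaps", "ProbabilityVolume", function(x) x@probs)

#' @rdname accessors
#' @export
setGeneric("regionMasks", function(x) standardGeneric("regionMasks"))
#' @rdname accessors
#' @export
setMethod("regionMasks", "ProbabilityVolume", function(x) x@regions)

## show methods ---------------------------------------------------------------

setMethod("show", "TimeGrid", function(object) {
  cat(sprintf(
    "TimeGrid: %d frames, %.3g s spacing; injection at frame %d (t = %.1f s); frames 1-%d excluded\n",
    nFrames(object), frameSpacing(object), object@injectionIndex,
    object@timepoints[object@injectionIndex], object@firstRetained - 1L))
})

setMethod("show", "AIFCurve", function(object) {
  cat(sprintf("AIFCurve: %d frames, peak %.4g 1/s at t = %.1f s\n",
              nFrames(object), max(object@values),
              object@grid@timepoints[which.max(object@values)]))
})

setMethod("show", "PKParams", function(object) {
  cat(sprintf("PKParams (model %d): vp = %.4g", object@modelOrder, object@vp))
  if (object@modelOrder >= 2L) cat(sprintf(", Ktrans = %.4g /min", object@ktrans))
  if (object@modelOrder >= 3L) cat(sprintf(", Kep = %.4g /min", object@kep))
  cat("\n")
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit (model %d): rss = %.6g on %d frames (%d free)\n",
              object@modelOrder, object@rss, object@nObs, object@nFree))
})

setMethod("show", "NMSVoxelResult", function(object) {
  cat(sprintf("NMSVoxelResult: label %d at CL = %.0f%%\n",
              object@label, 100 * object@confidenceLevel))
})

setMethod("show", "NMSVolumeResult", function(object) {
  tab <- tabulate(object@labelMap[object@mask], 3L)
  cat(sprintf(
    "NMSVolumeResult: %s volume, %d voxels in mask (CL = %.0f%%)\n  labels: M1 = %d, M2 = %d, M3 = %d\n",
    paste(dim(object@labelMap), collapse = " x "), sum(object@mask),
    100 * object@confidenceLevel, tab[1], tab[2], tab[3]))
})

setMethod("show", "SOMConfig", function(object) {
  cat(sprintf(
    "SOMConfig: %d x %d %s grid; radius %g -> 1 over %d ordering epochs; max %d epochs; init = %s\n",
    object@rows, object@cols, object@layout, object@initialRadius,
    object@orderingSteps, object@maxEpochs, object@init))
})

setMethod("show", "SOMModel", function(object) {
  cat(sprintf(
    "SOMModel: %d neurons, input dim %d; trained %d epochs (%s)\n",
    nrow(object@weights), ncol(object@weights), object@epochsTrained,
    if (object@converged) "converged" else "epoch limit"))
})

setMethod("show", "HitMap", function(object) {
  cat(sprintf("HitMap: %d neurons, %d profiles (labels: %d / %d / %d)\n",
              length(object@total), sum(object@total),
              sum(object@counts[, 1]), sum(object@counts[, 2]),
              sum(object@counts[, 3])))
})

setMethod("show", "NeuronProbabilityTable", function(object) {
  cat(sprintf("NeuronProbabilityTable: %d neurons (%d borrowed)\n",
              nrow(object@probs), sum(object@provenance > 0L)))
})

setMethod("show", "ProbabilityVolume", function(object) {
  cat(sprintf(
    "ProbabilityVolume: %s, tau = %.2f; region sizes M1 = %d, M2 = %d, M3 = %d\n",
    paste(dim(object@mask), collapse = " x "), object@tau,
    sum(object@regions[[1]]), sum(object@regions[[2]]),
    sum(object@regions[[3]])))
})

setMethod("show", "AveragedParameterMaps", function(object) {
  ok <- is.finite(object@vp)
  cat(sprintf(
    "AveragedParameterMaps: %s; mean vp = %.3f%%, mean Ktrans = %.4f /min\n",
    paste(dim(object@vp), collapse = " x "),
    mean(object@vp[ok]), mean(object@ktrans[is.finite(object@ktrans)])))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %s; core r = %g (M2), rim r = %g (M3); noise SD = %g x peak\n",
    paste(object@dim, collapse = " x "), object@coreRadius,
    object@rimRadius, object@noiseSd))
})

setMethod("show", "SyntheticStudy", function(object) {
  tab <- tabulate(object@labels[object@mask], 3L)
  cat(sprintf(
    "SyntheticStudy '%s': %s x %d frames; labels M1 = %d, M2 = %d, M3 = %d\n",
    object@animalId, paste(dim(object@labels), collapse = " x "),
    dim(object@dr1)[4], tab[1], tab[2], tab[3]))
})

setMethod("show", "EvaluationReport", function(object) {
  s <- object@summary
  cat(sprintf("EvaluationReport (k = %d folds)\n", object@k))
  cat(sprintf("  DSC Model 2: %.3f [%.3f, %.3f]\n",
              s$dsc_m2$mean, s$dsc_m2$ci[1], s$dsc_m2$ci[2]))
  cat(sprintf("  DSC Model 3: %.3f [%.3f, %.3f]\n",
              s$dsc_m3$mean, s$dsc_m3$ci[1], s$dsc_m3$ci[2]))
  cat(sprintf("  MPD vp = %.2f%%, Ktrans = %.2f%%, ve = %.2f%%\n",
              s$mpd$vp, s$mpd$ktrans, s$mpd$ve))
})
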