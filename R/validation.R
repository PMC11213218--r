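## Subject-level k-fold nested cross-validation of PNMS against NMS.
##
## Animals are permuted once and split into k non-overlapping test folds;
## the training set of each fold is drawn from the remaining animals to
## honor the train fraction. Per fold, a SOM is trained on the training
## animals' normalized labeled profiles and applied to the test animals;
## agreement is summarized by Dice similarity of the Model-2/3 regions
## (after masking out the Model-1 region at the probability threshold) and
## by mean percent differences of the permeability parameters.

#' Dice similarity coefficient
#'
#' 2|A intersect B| / (|A| + |B|). Two empty sets are defined to agree
#' perfectly (DSC = 1).
#'
#' @param a,b logical arrays/vectors on the same lattice, or integer index
#'   sets.
#' @return numeric in \[0, 1\].
#' @examples
#' dice(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
dice <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    if (length(a) != length(b)) .contract("masks must match in length")
    na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  } else {
    a <- as.integer(a); b <- as.integer(b)
    na <- length(a); nb <- length(b); ni <- length(intersect(a, b))
  }
  if (na + nb == 0L) return(1)
  2 * ni / (na + nb)
}

#' Mean percent difference of PNMS relative to NMS
#'
#' 100 x (pnms - nms) / nms. Undefined (NA, with a warning) for a zero
#' baseline.
#'
#' @param nmsValue baseline (conventional NMS) value.
#' @param pnmsValue probabilistic NMS value.
#' @return percent difference(s).
#' @examples
#' meanPercentDifference(13.649, 16.949)
#' @export
meanPercentDifference <- function(nmsValue, pnmsValue) {
  out <- 100 * (pnmsValue - nmsValue) / nmsValue
  zero <- !is.na(nmsValue) & nmsValue == 0
  if (any(zero)) {
    warning("zero NMS baseline: MPD undefined")
    out[zero] <- NA_real_
  }
  out
}

#' Random-permutation k-fold split at the animal level
#'
#' One random permutation of the animal ids; the k contiguous blocks are the
#' test folds (pairwise disjoint, union = all animals). The training set of
#' each fold is drawn from the remaining animals to honor `trainFraction`
#' (capped at all of them).
#'
#' @param animalIds vector of unique ids.
#' @param k number of folds (default 10).
#' @param trainFraction fraction of all animals used for training per fold
#'   (default 0.66).
#' @param seed integer seed.
#' @return list with elements `folds` (list of `list(train, test)`), `k`,
#'   `trainFraction`.
#' @export
makeFolds <- function(animalIds, k = 10L, trainFraction = 0.66, seed = 1L) {
  n <- length(animalIds)
  if (anyDuplicated(animalIds)) stop("animal ids must be unique")
  if (k > n) stop("k must not exceed the number of animals")
  set.seed(seed)
  perm <- sample(animalIds)
  testBlocks <- split(perm, cut(seq_len(n), k, labels = FALSE))
  nTrain <- min(round(trainFraction * n), n)
  folds <- lapply(testBlocks, function(test) {
    rest <- setdiff(perm, test)
    train <- if (length(rest) <= nTrain) rest else
      sample(rest, nTrain)
    list(train = train, test = test)
  })
  names(folds) <- NULL
  list(folds = folds, k = as.integer(k), trainFraction = trainFraction)
}

#' Percentile bootstrap confidence interval
#'
#' Seeded percentile bootstrap of the mean across fold-level values. A
#' single value yields a degenerate (point) interval.
#'
#' @param values numeric vector (e.g. per-fold means).
#' @param level confidence level (default 0.95).
#' @param nBoot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return numeric(2): lower and upper bounds.
#' @export
confidenceInterval <- function(values, level = 0.95, nBoot = 10000L,
                               seed = 1L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) return(c(NA_real_, NA_real_))
  if (length(values) == 1L) return(c(values, values))
  set.seed(seed)
  bs <- matrix(sample(values, length(values) * nBoot, replace = TRUE),
               nBoot)
  means <- rowMeans(bs)
  unname(stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

## fold-level means of the two techniques' parameters over their own regions
.foldParamMeans <- function(nmsRes, avgNms, avgPnms, pv) {
  mask <- nmsRes@mask
  lab <- nmsRes@labelMap
  reg <- pv@regions
  pnmsLeaky <- (reg[[2]] | reg[[3]]) & mask
  mn <- function(x, m) if (any(m)) mean(x[m], na.rm = TRUE) else NA_real_
  c(vpNMS = mn(avgNms@vp, mask),
    vpPNMS = mn(avgPnms@vp, mask & is.finite(avgPnms@vp)),
    ktransNMS = mn(avgNms@ktrans, mask & lab >= 2L),
    ktransPNMS = mn(avgPnms@ktrans, pnmsLeaky),
    veNMS = mn(avgNms@ve, mask & lab == 3L & is.finite(avgNms@ve)),
    vePNMS = mn(avgPnms@ve, reg[[3]] & is.finite(avgPnms@ve)))
}

#' Nested cross-validation of PNMS against NMS on a cohort
#'
#' Per fold: NMS label maps of the training animals tag their normalized
#' profiles; a SOM is batch-trained on those profiles and converted to a
#' neuron probability table; the test animals' voxels inherit their BMU's
#' probabilities. The Model-1 region at the probability threshold masks out
#' the brain, Dice coefficients of the Model-2/3 regions are computed
#' against the test animals' NMS regions, and mean permeability parameters
#' of both techniques (each over its own regions) give per-fold mean percent
#' differences. Folds where a model region is empty under both techniques
#' contribute DSC = 1; a fold with no finite baseline is dropped from that
#' parameter's average with a warning.
#'
#' @param cohort list of [SyntheticStudy-class] objects.
#' @param k number of folds (default 3 for desk-scale cohorts).
#' @param trainFraction training fraction per fold (default 0.66).
#' @param somCfg a [SOMConfig-class] template (seed is re-derived per fold).
#' @param confidenceLevel NMS F-test confidence level (default 0.95).
#' @param tau PNMS region threshold (default 0.5).
#' @param kepFloor smallest usable Kep for ve (1/min).
#' @param seed global seed for folds, SOM seeds and the bootstrap.
#' @param nmsResults optional precomputed list of [NMSVolumeResult-class]
#'   (one per cohort animal), to avoid refitting.
#' @param nBoot bootstrap resamples for the CIs.
#' @return an [EvaluationReport-class].
#' @export
runNestedCV <- function(cohort, k = 3L, trainFraction = 0.66,
                        somCfg = somConfig(), confidenceLevel = 0.95,
                        tau = 0.5, kepFloor = 1e-3, seed = 1L,
                        nmsResults = NULL, nBoot = 10000L) {
  n <- length(cohort)
  ids <- vapply(cohort, function(s) s@animalId, character(1))
  if (anyDuplicated(ids)) stop("cohort animal ids must be unique")
  names(cohort) <- ids

  if (is.null(nmsResults)) {
    nmsResults <- lapply(cohort, fitVolume, confidenceLevel = confidenceLevel)
  }
  names(nmsResults) <- ids
  profiles <- lapply(cohort, .studyProfiles)
  labels <- lapply(ids, function(id) {
    res <- nmsResults[[id]]
    res@labelMap[res@mask]
  })
  names(labels) <- ids
  avgNms <- lapply(nmsResults, nmsSelectedMaps, kepFloor = kepFloor)

  split <- makeFolds(ids, k, trainFraction, seed = deriveSeed(seed, "folds"))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    fold <- split$folds[[f]]
    trainX <- do.call(rbind, profiles[fold$train])
    trainY <- unlist(labels[fold$train], use.names = FALSE)
    cfg <- somCfg
    cfg@seed <- deriveSeed(seed, paste0("som-fold", f))
    som <- batchTrain(trainX, cfg)
    tab <- neuronProbabilities(computeHitMap(som, trainX, trainY), som)

    dscNum <- c(m2 = 0, m3 = 0)
    dscDen <- c(m2 = 0, m3 = 0)
    pm <- matrix(NA_real_, length(fold$test), 6,
                 dimnames = list(NULL, c("vpNMS", "vpPNMS", "ktransNMS",
                                         "ktransPNMS", "veNMS", "vePNMS")))
    for (t in seq_along(fold$test)) {
      id <- fold$test[t]
      res <- nmsResults[[id]]
      pv <- voxelProbabilities(profiles[[id]], som, tab, res@mask, tau)
      lab <- res@labelMap
      for (m in 2:3) {
        key <- paste0("m", m)
        A <- pv@regions[[m]]
        B <- lab == m & res@mask
        dscNum[key] <- dscNum[key] + 2 * sum(A & B)
        dscDen[key] <- dscDen[key] + sum(A) + sum(B)
      }
      avgP <- pnmsParameterMaps(res, pv, kepFloor)
      pm[t, ] <- .foldParamMeans(res, avgNms[[id]], avgP, pv)
    }
    dsc <- ifelse(dscDen == 0, 1, dscNum / dscDen)
    if (any(dscDen == 0))
      warning(sprintf("fold %d: empty model region under both techniques", f))
    means <- colMeans(pm, na.rm = TRUE)
    rows[[f]] <- data.frame(fold = f, dscM2 = dsc["m2"], dscM3 = dsc["m3"],
                            t(means))
  }
  perFold <- do.call(rbind, rows)
  rownames(perFold) <- NULL
  perFold$mpdVp <- meanPercentDifference(perFold$vpNMS, perFold$vpPNMS)
  perFold$mpdKtrans <- meanPercentDifference(perFold$ktransNMS,
                                             perFold$ktransPNMS)
  perFold$mpdVe <- meanPercentDifference(perFold$veNMS, perFold$vePNMS)

  ciseed <- deriveSeed(seed, "bootstrap")
  ci <- function(v) confidenceInterval(v, nBoot = nBoot, seed = ciseed)
  s <- list(
    dsc_m2 = list(mean = mean(perFold$dscM2), ci = ci(perFold$dscM2)),
    dsc_m3 = list(mean = mean(perFold$dscM3), ci = ci(perFold$dscM3)),
    vp = list(nms = mean(perFold$vpNMS, na.rm = TRUE),
              pnms = mean(perFold$vpPNMS, na.rm = TRUE),
              nms_ci = ci(perFold$vpNMS), pnms_ci = ci(perFold$vpPNMS)),
    ktrans = list(nms = mean(perFold$ktransNMS, na.rm = TRUE),
                  pnms = mean(perFold$ktransPNMS, na.rm = TRUE),
                  nms_ci = ci(perFold$ktransNMS),
                  pnms_ci = ci(perFold$ktransPNMS)),
    ve = list(nms = mean(perFold$veNMS, na.rm = TRUE),
              pnms = mean(perFold$vePNMS, na.rm = TRUE),
              nms_ci = ci(perFold$veNMS), pnms_ci = ci(perFold$vePNMS)))
  s$mpd <- list(
    vp = meanPercentDifference(s$vp$nms, s$vp$pnms),
    ktrans = meanPercentDifference(s$ktrans$nms, s$ktrans$pnms),
    ve = meanPercentDifference(s$ve$nms, s$ve$pnms))
  new("EvaluationReport", perFold = perFold, summary = s, k = as.integer(k))
}

#' Write an evaluation report to disk
#'
#' Per-fold rows as CSV plus a JSON summary (means, CI bounds and MPD per
#' parameter, mirroring a mean/CI-LB/CI-UB/MPD table layout).
#'
#' @param report an [EvaluationReport-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeEvaluationReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@perFold, file.path(dir, "evaluation_folds.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report@summary,
                       file.path(dir, "evaluation_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
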