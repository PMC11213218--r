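## Batch-trained Kohonen self-organizing map on a hexagonal lattice.
##
## Each epoch assigns every profile to its best matching unit (BMU, minimum
## Euclidean distance, ties to the lowest neuron index) and then replaces
## every prototype with the neighborhood-kernel-weighted mean of all
## profiles. The kernel is Gaussian over lattice distance with sigma equal to
## the current radius; the radius decays linearly from `initialRadius` to 1
## across the ordering-phase epochs and is then held at 1 (tuning phase).
## Training stops early once BMU assignments no longer change after the
## ordering phase (a fixed point of the batch update).

#' Hexagonal lattice geometry for a SOM configuration
#'
#' Offset-row hexagonal packing: odd rows are shifted half a unit, rows are
#' sqrt(3)/2 apart, so all interior nearest-neighbor distances are 1.
#'
#' @param config a [SOMConfig-class].
#' @return a [SOMGrid-class].
#' @examples
#' g <- hexDistances(somConfig(rows = 2, cols = 2))
#' gridDistances(g)
#' @export
hexDistances <- function(config) {
  stopifnot(is(config, "SOMConfig"))
  validObject(config)
  rows <- config@rows
  cols <- config@cols
  r <- rep(seq_len(rows) - 1L, each = cols)
  c_ <- rep(seq_len(cols) - 1L, rows)
  coords <- cbind(x = c_ + 0.5 * (r %% 2), y = r * sqrt(3) / 2)
  new("SOMGrid", coords = coords,
      distances = as.matrix(stats::dist(coords)))
}

#' Deterministic linear initialization of SOM prototypes
#'
#' Prototypes are laid out on the plane spanned by the first two principal
#' directions of the data, scaled to two standard deviations along each, and
#' centered on the data mean. Eigenvector signs are fixed (largest-magnitude
#' loading positive), so the initialization is fully deterministic. With
#' `init = "random"` in the config, prototypes are instead a seeded sample of
#' input profiles.
#'
#' @param data numeric matrix, one normalized profile per row.
#' @param config a [SOMConfig-class].
#' @param grid optional precomputed [SOMGrid-class].
#' @return numeric weight matrix (neurons x input dimension).
#' @export
initWeights <- function(data, config, grid = hexDistances(config)) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) .degenerate("need at least 2 profiles")
  ctr <- colMeans(data)
  Xc <- sweep(data, 2, ctr)
  if (max(abs(Xc)) == 0) .degenerate("all profiles are identical")
  if (config@init == "random") {
    set.seed(config@seed)
    ix <- sample.int(nrow(data), config@rows * config@cols, replace = TRUE)
    return(data[ix, , drop = FALSE])
  }
  cv <- crossprod(Xc) / (nrow(data) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  fixSign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  v1 <- fixSign(eg$vectors[, 1])
  sd1 <- sqrt(max(eg$values[1], 0))
  if (ncol(data) >= 2L) {
    v2 <- fixSign(eg$vectors[, 2])
    sd2 <- sqrt(max(eg$values[2], 0))
  } else {
    v2 <- 0 * v1
    sd2 <- 0
  }
  co <- grid@coords
  a1 <- if (diff(range(co[, 1])) > 0)
    2 * (2 * (co[, 1] - min(co[, 1])) / diff(range(co[, 1])) - 1) else
    rep(0, nrow(co))
  a2 <- if (diff(range(co[, 2])) > 0)
    2 * (2 * (co[, 2] - min(co[, 2])) / diff(range(co[, 2])) - 1) else
    rep(0, nrow(co))
  matrix(ctr, nrow(co), length(ctr), byrow = TRUE) +
    outer(a1 * sd1, v1) + outer(a2 * sd2, v2)
}

## BMU indices for the rows of X given prototypes W (rows), vectorized via
## the expansion ||x - w||^2 = ||x||^2 - 2 x.w + ||w||^2 (the ||x||^2 term is
## constant per profile and dropped). Ties resolve to the lowest index.
.bmuIndex <- function(X, W) {
  score <- 2 * (X %*% t(W))
  score <- sweep(score, 2, rowSums(W * W))
  max.col(score, ties.method = "first")
}

#' Best matching unit lookup
#'
#' Index of the prototype nearest (Euclidean) to each profile; ties break to
#' the lowest neuron index.
#'
#' @param weights a [SOMModel-class] or a prototype matrix (neurons x dim).
#' @param profiles a numeric vector (one profile) or matrix (one per row).
#' @return integer vector of neuron indices.
#' @export
findBMU <- function(weights, profiles) {
  W <- if (is(weights, "SOMModel")) weights@weights else as.matrix(weights)
  X <- if (is.matrix(profiles)) profiles else matrix(profiles, nrow = 1)
  if (ncol(X) != ncol(W)) .contract("profile dimension mismatch")
  if (any(!is.finite(X))) stop("profiles must be finite")
  .bmuIndex(X, W)
}

.radiusSchedule <- function(config, epoch) {
  if (epoch >= config@orderingSteps || config@orderingSteps == 1L) return(1)
  config@initialRadius +
    (1 - config@initialRadius) * (epoch - 1) / (config@orderingSteps - 1)
}

#' Batch-train a self-organizing map
#'
#' @param data numeric matrix of normalized profiles, one per row.
#' @param config a [SOMConfig-class].
#' @return a [SOMModel-class].
#' @examples
#' cfg <- somConfig(rows = 2, cols = 3, orderingSteps = 10, maxEpochs = 30)
#' x <- matrix(rnorm(600), 100, 6)
#' m <- batchTrain(x, cfg)
#' m
#' @export
batchTrain <- function(data, config) {
  data <- as.matrix(data)
  if (!nrow(data)) .degenerate("empty training data")
  grid <- hexDistances(config)
  n_ <- config@rows * config@cols
  if (max(abs(sweep(data, 2, data[1, ]))) == 0) {
    ## all profiles identical: the batch update's fixed point is that profile
    return(new("SOMModel", config = config, grid = grid,
               weights = matrix(data[1, ], n_, ncol(data), byrow = TRUE),
               epochsTrained = 0L, converged = TRUE))
  }
  W <- initWeights(data, config, grid)
  n <- nrow(W)
  d2 <- grid@distances^2
  prevBmu <- NULL
  kernel <- NULL
  lastR <- NA_real_
  epochs <- 0L
  converged <- FALSE
  for (e in seq_len(config@maxEpochs)) {
    bmu <- .bmuIndex(data, W)
    if (!is.null(prevBmu) && e > config@orderingSteps &&
        identical(bmu, prevBmu)) {
      converged <- TRUE
      break
    }
    r <- .radiusSchedule(config, e)
    if (!identical(r, lastR)) {
      kernel <- exp(-d2 / (2 * r^2))
      lastR <- r
    }
    counts <- tabulate(bmu, n)
    S <- matrix(0, n, ncol(data))
    agg <- rowsum(data, group = bmu)
    S[as.integer(rownames(agg)), ] <- agg
    W <- (kernel %*% S) / drop(kernel %*% counts)
    prevBmu <- bmu
    epochs <- e
  }
  dimnames(W) <- NULL
  new("SOMModel", config = config, grid = grid, weights = W,
      epochsTrained = epochs, converged = converged)
}

#' Labeled BMU hit map
#'
#' Counts, per neuron, how many profiles map to it overall and per
#' nested-model label.
#'
#' @param model a [SOMModel-class] (or prototype matrix).
#' @param data profile matrix, one per row.
#' @param labels integer vector of per-profile model labels (1, 2 or 3).
#' @return a [HitMap-class].
#' @export
computeHitMap <- function(model, data, labels) {
  data <- as.matrix(data)
  labels <- as.integer(labels)
  if (length(labels) != nrow(data)) .contract("labels length mismatch")
  if (length(labels) && !all(labels %in% 1:3))
    stop("labels must be 1, 2 or 3")
  W <- if (is(model, "SOMModel")) model@weights else as.matrix(model)
  n <- nrow(W)
  bmu <- findBMU(W, data)
  counts <- vapply(1:3, function(l) tabulate(bmu[labels == l], n),
                   integer(n))
  new("HitMap", counts = counts, total = as.integer(rowSums(counts)))
}

#' Mean quantization error
#'
#' Mean Euclidean distance between each profile and its BMU prototype; the
#' standard SOM goodness-of-fit diagnostic.
#'
#' @param model a [SOMModel-class] (or prototype matrix).
#' @param data profile matrix, one per row.
#' @return numeric scalar.
#' @export
quantizationError <- function(model, data) {
  data <- as.matrix(data)
  if (!nrow(data)) .degenerate("empty data")
  W <- if (is(model, "SOMModel")) model@weights else as.matrix(model)
  bmu <- findBMU(W, data)
  diff <- data - W[bmu, , drop = FALSE]
  mean(sqrt(rowSums(diff * diff)))
}

#' Persist and restore a trained SOM
#'
#' The model is stored as a single JSON container holding the configuration,
#' lattice coordinates and the full-precision weight matrix.
#'
#' @param model a [SOMModel-class].
#' @param path file path (.json).
#' @return `readSOM` returns a [SOMModel-class]; `writeSOM` returns the path
#'   invisibly.
#' @export
writeSOM <- function(model, path) {
  cfg <- model@config
  jsonlite::write_json(list(
    config = list(rows = cfg@rows, cols = cfg@cols, layout = cfg@layout,
                  initial_radius = cfg@initialRadius,
                  ordering_steps = cfg@orderingSteps,
                  max_epochs = cfg@maxEpochs, init = cfg@init,
                  seed = cfg@seed),
    epochs_trained = model@epochsTrained,
    converged = model@converged,
    coords = model@grid@coords,
    weights = model@weights
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeSOM
#' @export
readSOM <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- somConfig(rows = x$config$rows, cols = x$config$cols,
                   layout = x$config$layout,
                   initialRadius = x$config$initial_radius,
                   orderingSteps = x$config$ordering_steps,
                   maxEpochs = x$config$max_epochs, init = x$config$init,
                   seed = x$config$seed)
  new("SOMModel", config = cfg, grid = hexDistances(cfg),
      weights = as.matrix(x$weights),
      epochsTrained = as.integer(x$epochs_trained),
      converged = as.logical(x$converged))
}

#' Export a hit map as CSV
#'
#' Columns: neuron_row, neuron_col, hits_total, hits_m1, hits_m2, hits_m3.
#'
#' @param hitmap a [HitMap-class].
#' @param config the [SOMConfig-class] giving the lattice shape.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeHitMapCsv <- function(hitmap, config, path) {
  n <- length(hitmap@total)
  row <- (seq_len(n) - 1L) %/% config@cols + 1L
  col <- (seq_len(n) - 1L) %% config@cols + 1L
  utils::write.csv(data.frame(
    neuron_row = row, neuron_col = col,
    hits_total = hitmap@total,
    hits_m1 = hitmap@counts[, 1], hits_m2 = hitmap@counts[, 2],
    hits_m3 = hitmap@counts[, 3]), path, row.names = FALSE)
  invisible(path)
}
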