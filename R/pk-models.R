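## Forward evaluation of the three nested Patlak-family models on a shared
## acquisition grid.
##
##   Model 1:  C_t(t) = vp * C_a(t)
##   Model 2:  C_t(t) = vp * C_a(t) + Ktrans * Int_0^t C_a(l) dl
##   Model 3:  C_t(t) = vp * C_a(t) + Ktrans * Int_0^t C_a(l) e^{-Kep (t-l)} dl
##
## Times are seconds internally; Ktrans and Kep are accepted and reported in
## 1/min and converted at the operation boundary.

.aifVals <- function(aif) if (is(aif, "AIFCurve")) aif@values else as.numeric(aif)

#' Running trapezoidal integral of a curve
#'
#' Per-frame cumulative integral of an AIF (or any per-frame curve) by the
#' trapezoidal rule on the acquisition grid; the first element is 0.
#'
#' @param aif an [AIFCurve-class] or numeric vector on `grid`.
#' @param grid a [TimeGrid-class].
#' @return numeric vector of the same length (units: input units x seconds).
#' @examples
#' g <- timeGrid(10, 1, injectionTime = 0, excludeFrames = 0)
#' cumulativeIntegral(rep(1, 10), g)  # equals t - t0
#' @export
cumulativeIntegral <- function(aif, grid) {
  v <- .aifVals(aif)
  if (length(v) != nFrames(grid))
    .contract("curve and grid lengths differ")
  as.numeric(pracma::cumtrapz(grid@timepoints, v))
}

#' Convolution of a curve with a decaying exponential
#'
#' Evaluates `Int_0^t curve(l) e^{-kep (t - l)} dl` at every frame, with the
#' curve interpolated piecewise-linearly between frames; the per-interval
#' integral is analytic, and the running value follows the exact O(n)
#' recursion `y_k = e^{-kep dt} y_{k-1} + I_k`. With `kep = 0` this reduces
#' exactly to [cumulativeIntegral()].
#'
#' @param aif an [AIFCurve-class] or numeric vector on `grid`.
#' @param kep reverse transfer constant in 1/min (converted internally).
#' @param grid a [TimeGrid-class].
#' @return numeric vector of per-frame convolution values.
#' @export
expConvolution <- function(aif, kep, grid) {
  if (length(kep) != 1L || !is.finite(kep) || kep < 0)
    stop("kep must be a single non-negative number")
  v <- .aifVals(aif)
  if (length(v) != nFrames(grid))
    .contract("curve and grid lengths differ")
  if (kep == 0) return(cumulativeIntegral(v, grid))
  a <- kep / 60                     # 1/min -> 1/s
  dt <- frameSpacing(grid)
  ad <- a * dt
  e <- exp(-ad)
  if (ad < 1e-4) {
    # series forms avoid cancellation for very small kep * dt
    A0 <- dt * (1 - ad / 2 + ad^2 / 6)
    A1 <- dt^2 * (1 / 2 - ad / 3 + ad^2 / 8)
  } else {
    A0 <- (1 - e) / a
    A1 <- dt * (1 - e) / a - (1 - e * (1 + ad)) / a^2
  }
  n <- length(v)
  c0 <- v[-n]
  c1 <- v[-1]
  incr <- c0 * A0 + (c1 - c0) * (A1 / dt)
  y <- stats::filter(incr, e, method = "recursive")
  c(0, as.numeric(y))
}

#' Evaluate a nested pharmacokinetic model
#'
#' Forward-evaluates the model selected by `params@modelOrder` for a given
#' arterial input function. Model 2 with `ktrans = 0` equals Model 1; Model 3
#' with `kep = 0` equals Model 2.
#'
#' @param params a [PKParams-class].
#' @param aif an [AIFCurve-class] or numeric vector on `grid`.
#' @param grid a [TimeGrid-class].
#' @return numeric vector: the tissue delta-R1 trace (1/s) per frame.
#' @examples
#' g <- timeGrid()
#' a <- makeAIF(g)
#' tr <- evalModel(pkParams(vp = 0.02, ktrans = 0.1, kep = 1), a, g)
#' @export
evalModel <- function(params, aif, grid) {
  stopifnot(is(params, "PKParams"))
  validObject(params)
  v <- .aifVals(aif)
  base <- params@vp * v
  kt <- params@ktrans / 60          # 1/min -> 1/s
  switch(params@modelOrder,
    base,
    base + kt * cumulativeIntegral(v, grid),
    base + kt * expConvolution(v, params@kep, grid)
  )
}

#' Simulate a population arterial input function
#'
#' Gamma-variate first pass plus a slower recirculation/washout term, zero
#' before the injection frame, with the peak normalized to `peak`. The bolus
#' shape is `(tau/tp)^alpha exp(alpha (1 - tau/tp))` (unit peak at
#' `tau = tp`); recirculation is `recircFrac (1 - e^{-tau/recircRise})
#' e^{-tau/washoutTau}`.
#'
#' @param grid a [TimeGrid-class].
#' @param peak peak amplitude in delta-R1 units (1/s), default 3.
#' @param alpha gamma-variate shape (> 0), default 3.
#' @param tp time-to-peak of the first pass in seconds, default 12.
#' @param recircFrac recirculation plateau as a fraction of the bolus peak.
#' @param recircRise recirculation rise time constant (s).
#' @param washoutTau washout time constant (s).
#' @return an [AIFCurve-class].
#' @export
makeAIF <- function(grid, peak = 3, alpha = 3, tp = 12,
                    recircFrac = 0.3, recircRise = 30, washoutTau = 300) {
  if (alpha <= 0 || tp <= 0 || recircRise <= 0 || washoutTau <= 0)
    stop("AIF shape parameters must be positive")
  t0 <- grid@timepoints[grid@injectionIndex]
  tau <- pmax(grid@timepoints - t0, 0)
  bolus <- ifelse(tau > 0, (tau / tp)^alpha * exp(alpha * (1 - tau / tp)), 0)
  recirc <- recircFrac * (1 - exp(-tau / recircRise)) * exp(-tau / washoutTau)
  raw <- bolus + recirc
  raw[seq_len(grid@injectionIndex - 1L)] <- 0
  aifCurve(raw / max(raw) * peak, grid)
}

#' Read and write AIF curves
#'
#' CSV carries two columns (`time_s`, `value`); JSON additionally embeds the
#' grid metadata (spacing, frame count, injection frame, first retained
#' frame) so the curve round-trips with its [TimeGrid-class].
#'
#' @param aif an [AIFCurve-class].
#' @param path file path.
#' @return `readAIFJson` returns an [AIFCurve-class]; `readAIFCsv` returns a
#'   data.frame; writers return the path invisibly.
#' @export
writeAIFCsv <- function(aif, path) {
  utils::write.csv(
    data.frame(time_s = timePoints(aif), value = aifValues(aif)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAIFCsv
#' @export
readAIFCsv <- function(path) {
  utils::read.csv(path)
}

#' @rdname writeAIFCsv
#' @export
writeAIFJson <- function(aif, path) {
  g <- acqGrid(aif)
  jsonlite::write_json(list(
    grid = list(n_frames = nFrames(g), spacing_s = frameSpacing(g),
                injection_index = g@injectionIndex,
                first_retained = g@firstRetained),
    values = aifValues(aif)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAIFCsv
#' @export
readAIFJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- new("TimeGrid",
           timepoints = (seq_len(x$grid$n_frames) - 1) * x$grid$spacing_s,
           injectionIndex = as.integer(x$grid$injection_index),
           firstRetained = as.integer(x$grid$first_retained))
  aifCurve(x$values, g)
}
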