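# Shared fixtures: a shortened acquisition grid keeps unit tests fast while
# preserving the structure (pre-injection baseline, excluded frames, bolus).

smallGrid <- function(n = 150L, spacing = 1.55, injectionTime = 40,
                      exclude = 15L) {
  timeGrid(n, spacing, injectionTime, exclude)
}

smallAIF <- function(grid = smallGrid(), ...) makeAIF(grid, ...)

# dense-grid brute-force oracle for the exponential convolution: trapezoidal
# integration of the linearly interpolated curve times the exponential kernel,
# evaluated at every coarse frame via a single cumulative pass
denseConvOracle <- function(values, kep, grid, dt = 0.001) {
  tp <- timePoints(grid)
  a <- kep / 60
  td <- seq(tp[1], tp[length(tp)], by = dt)
  vd <- approx(tp, values, xout = td)$y
  ct <- pracma::cumtrapz(td, vd * exp(a * td))
  idx <- round((tp - tp[1]) / dt) + 1
  exp(-a * tp) * ct[idx]
}

# one-hot probability volume matching an NMS label map (P = 1 for the
# selected model), used for degenerate-equivalence checks
oneHotProbVolume <- function(nmsRes, tau = 0.5) {
  lab <- nmsRes@labelMap
  mask <- nmsRes@mask
  d <- dim(mask)
  probs <- array(NA_real_, c(d, 3))
  for (m in 1:3) {
    pm <- array(NA_real_, d)
    pm[mask] <- as.numeric(lab[mask] == m)
    probs[, , , m] <- pm
  }
  regions <- lapply(1:3, function(m) lab == m & mask)
  new("ProbabilityVolume", probs = probs, mask = mask, tau = tau,
      regions = regions)
}

# small noiseless or noisy phantom study
smallStudy <- function(noiseSd = 0, dim = c(12L, 12L, 1L), seed = 7L,
                       grid = smallGrid(), aif = smallAIF(grid)) {
  spec <- phantomSpec(dim = dim, coreRadius = 2.5, rimRadius = 4.5,
                      noiseSd = noiseSd, seed = seed)
  simulateStudy(spec, grid, aif)
}
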