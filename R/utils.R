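## Deterministic seed derivation: every stochastic stage gets its own stream
## derived from the single global seed, so one integer reproduces a full run.

#' Derive a stage seed from a global seed
#'
#' Polynomial hash of a tag string folded with the global seed, reduced
#' modulo 2^31 - 1 so the result is always a valid R integer seed. All
#' arithmetic stays below 2^53, so the result is exact and platform-stable.
#'
#' @param seed global integer seed.
#' @param tag character tag naming the consumer (e.g. "folds", "animal3").
#' @return an integer in 0 ... 2^31 - 2.
#' @export
deriveSeed <- function(seed, tag) {
  h <- 17
  for (b in utf8ToInt(tag)) h <- (h * 69069 + b) %% 2147483647
  as.integer((h + (abs(as.numeric(seed)) %% 2147483647) * 40503) %% 2147483647)
}

## error helpers keeping message style uniform
.degenerate <- function(msg) stop("degenerate input: ", msg, call. = FALSE)
.contract <- function(msg) stop("contract violation: ", msg, call. = FALSE)
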