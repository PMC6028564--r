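#' @useDynLib rnnclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor pchisq pt rnorm runif
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a fixed Mersenne-Twister seed, restoring the caller's
# RNG state afterwards so library code never clobbers the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Derive a member seed from a base seed and an index
#'
#' Deterministic mixing of a base seed with a stream index (multiplicative
#' congruential step modulo the Mersenne prime 2^31 - 1), so that ensemble
#' members get independent, reproducible RNG streams regardless of the order
#' in which they are trained.
#'
#' @param seed Integer base seed.
#' @param index Positive integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + as.numeric(index) * 16807 + 1) %% m
  s <- (s * 48271 + 1) %% m
  as.integer(s)
}

stop_ctx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 1
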