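#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd cor fft mvfft rnorm runif approx splinefun
#'   quantile setNames aggregate
#' @importFrom utils head tail read.csv write.csv packageVersion
NULL

## Run code under a fixed RNG seed, restoring the caller's RNG state after.
## All generator functions route randomness through this so that any output is
## a pure function of its arguments (including the seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

## ms -> integer sample count, at least 1
ms_to_samples <- function(ms, fs_hz) {
  max(1L, as.integer(round(ms * fs_hz / 1000)))
}

## nearest odd sample count for a symmetric window
ms_to_odd_samples <- function(ms, fs_hz) {
  n <- ms_to_samples(ms, fs_hz)
  if (n %% 2L == 0L) n + 1L else n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
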