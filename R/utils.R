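#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft quantile rnorm runif prcomp sd median approx
#' @importFrom utils head tail write.csv read.csv
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Remove the least-squares linear trend from a numeric vector.
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) return(x - mean(x))
  t <- seq_len(n)
  tc <- t - mean(t)
  x - mean(x) - tc * (sum(tc * x) / sum(tc * tc))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
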