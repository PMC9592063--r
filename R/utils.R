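# Internal helpers shared across modules.

#' @useDynLib emg2prosody, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx convolve fft mvfft rnorm runif sd var cor
#'   setNames quantile predict prcomp pnorm dnorm median cov acf
#' @importFrom utils head tail read.table write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one user-facing seed into per-stage /
#' per-component seeds. Uses a Weyl-style integer recurrence so nearby master
#' seeds do not collide across streams; result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed master seed (single integer).
#' @param stream character scalar naming the consumer (e.g. `"synth"`,
#'   `"train"`).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483629 + 1)
}

# run expr with a local RNG state so callers' streams are not disturbed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
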