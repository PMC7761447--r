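## Internal helpers: seeded sub-streams and argument checks.

#' @useDynLib ibwgp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Derive a reproducible sub-seed from a master seed and a stream name, so
## each stage of the simulator draws from its own stream. Kept below 2^31.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) %% 2147480000 + h * 1009) %% 2147483647)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ibwgp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
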