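#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All stochastic entry points funnel through this so that a seed argument never
# clobbers the user's global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a master seed; kept below 2^31.
child_seed <- function(seed, index) {
  (as.double(seed) * 7919 + 104729 * as.double(index)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)

# sample() without the length-1 surprise
sample_int <- function(n, size, replace = FALSE, prob = NULL) {
  sample.int(n, size = size, replace = replace, prob = prob)
}
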