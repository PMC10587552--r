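# Seeded-execution helpers.
#
# All stochastic operations take an explicit integer seed and restore the
# caller's RNG state on exit, so library code never perturbs a user's random
# stream and identical seeds give identical output.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite integer", call. = FALSE)
  }
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
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based derivation of per-subject seeds from one master seed, so each
# subject is independently reproducible. Lehmer-style mix kept inside 31 bits
# (exact in double arithmetic: 48271 * x < 2^47 < 2^53).
derive_seed <- function(master, index) {
  m <- 2147483647
  x <- (abs(as.numeric(master)) %% (m - 1)) + 1
  for (k in seq_len(2)) {
    x <- (48271 * x + 12345 + as.numeric(index) * 2654435) %% m
    if (x == 0) x <- 1
  }
  as.integer(x)
}
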