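# Seeded-RNG helper: runs `code` under a Mersenne-Twister stream seeded with
# `seed`, restoring the caller's RNG state afterwards. All randomness in the
# package flows through this so that every artifact is reproducible from its
# recorded integer seed.
#' @noRd
with_rng_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    rlang::abort("rng_seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x
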