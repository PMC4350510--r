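#' @keywords internal
"_PACKAGE"

# Deterministic seed hierarchy: every stage (cohort -> participant ->
# schedule/session) derives its own 31-bit seed from a parent seed and an
# index, so any single participant can be re-simulated in isolation.
# splitmix64-style integer mixing, kept in double precision below 2^53 and
# reduced mod 2^31 - 1 (R's set.seed() takes a 32-bit integer).
derive_seed <- function(seed, index, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  x <- (abs(seed) * 2654435761 + index * 40503 + stream * 69621) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x)
}

# Evaluate expr with a local RNG state seeded by `seed` (NULL = use the
# current stream), restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# longest run of TRUE (or of identical values when x is not logical)
longest_run <- function(x) {
  if (length(x) == 0L) return(0L)
  if (is.logical(x)) {
    r <- rle(x)
    runs <- r$lengths[r$values]
    if (length(runs) == 0L) 0L else max(runs)
  } else {
    max(rle(as.character(x))$lengths)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
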