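.assertSeed <- function(seed) {
  if (length(seed) != 1 || is.na(seed) || seed != round(seed))
    stop("seed must be a single integer", call. = FALSE)
  as.integer(seed)
}

.assertProb <- function(p, what) {
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop(sprintf("%s must be a probability in [0, 1]", what), call. = FALSE)
  as.numeric(p)
}

# All stochastic operations run under withr::with_seed so no global RNG
# state leaks in or out.
.withSeed <- function(seed, code) {
  withr::with_seed(.assertSeed(seed), code)
}

.assertVertexSet <- function(g, v, what = "vertex set") {
  n <- numVertices(g)
  v <- as.integer(v)
  if (length(v) == 0) stop(sprintf("%s must be non-empty", what), call. = FALSE)
  if (anyDuplicated(v)) stop(sprintf("%s has duplicates", what), call. = FALSE)
  if (min(v) < 1 || max(v) > n)
    stop(sprintf("%s out of range [1, %d]", what, n), call. = FALSE)
  v
}
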