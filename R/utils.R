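# Internal helpers shared across modules.

# Evaluate expr with a local RNG state seeded at `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user code.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

stopifnotScalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}

# Fast centered moving average via cumulative sums; pads ends by shrinking
# the window symmetrically.
movingAverage <- function(x, halfWidth) {
  n <- length(x)
  if (halfWidth < 1L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - halfWidth, 1L)
  hi <- pmin(i + halfWidth, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Sample count for a duration at a given rate; ties round to even.
durationToSamples <- function(duration, sampleRate) {
  as.integer(round(duration * sampleRate))
}
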