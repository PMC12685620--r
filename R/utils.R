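# Internal helpers shared across modules.

# Evaluate `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards. Keeps the phantom a pure function of
# (config, seed) without clobbering user randomness.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

vnorm <- function(x) sqrt(sum(x^2))

# Smooth raised-cosine window: 0 outside [start, start+duration], 1 in the
# plateau, half-cosine ramps of length `ramp` at both ends.
cos_window <- function(t, start, duration, ramp) {
  ramp <- min(ramp, duration / 2)
  w <- numeric(length(t))
  if (ramp <= 0) {
    w[t >= start & t <= start + duration] <- 1
    return(w)
  }
  up <- t >= start & t < start + ramp
  mid <- t >= start + ramp & t <= start + duration - ramp
  down <- t > start + duration - ramp & t <= start + duration
  w[up] <- 0.5 * (1 - cos(pi * (t[up] - start) / ramp))
  w[mid] <- 1
  w[down] <- 0.5 * (1 - cos(pi * (start + duration - t[down]) / ramp))
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
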