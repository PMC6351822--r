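# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

cf_stop <- function(...) stop(..., call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!(is.numeric(seed) && length(seed) == 1L && is.finite(seed)))
    cf_stop("`seed` must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-sample seed stream derived from a top-level seed.
# Stays below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  (((seed %% 100003) * 10007 + index * 7919 + 104729) %% 2147483629) + 1
}

# Integer fragment lengths from a normal(mean, sd) truncated to [min, max].
rtrunc_lengths <- function(n, mean, sd, min, max) {
  lo <- pnorm(min - 0.5, mean, sd)
  hi <- pnorm(max + 0.5, mean, sd)
  x <- qnorm(runif(n, lo, hi), mean, sd)
  pmin(pmax(as.integer(round(x)), as.integer(min)), as.integer(max))
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}
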