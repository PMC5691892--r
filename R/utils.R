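# Evaluate `code` under set.seed(seed), restoring the caller's RNG state so
# package functions never disturb the global stream.
.with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
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

# Integer-ish validation.
.check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop("`", name, "` must be an integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}
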