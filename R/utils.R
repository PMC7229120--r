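# Internal helpers shared across modules.

# Deterministic substream seed for (experiment seed, session, neuron).
# neuron = 0 is the behavior stream, session = 0 the ground-truth stream.
# Kept below 2^31 so set.seed() always accepts it.
derive_seed <- function(seed, session, neuron) {
  s <- (abs(seed) %% 1000003) * 2039 + session * 499979 + neuron * 7919
  as.integer(s %% 2147483629) + 1L
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG.
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in '%s': %s", field, msg), call. = FALSE)
}

check_scalar_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a single probability in [0, 1]")
  invisible(x)
}

check_positive <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop_config(field, if (strict) "must be > 0" else "must be >= 0")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_config(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

# Circular difference of two orientations in degrees (mod 180), in [0, 90].
orientation_diff <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
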