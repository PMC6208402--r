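# Internal helpers: seed splitting, argument checks, logit scale.

# Derive a reproducible sub-stream seed for a named pipeline stage from the
# master seed. Keeps all stages independently reproducible from one integer
# without consuming the caller's RNG state.
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# evaluate expr with a local RNG seeded at `seed`, restoring state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
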