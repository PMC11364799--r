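# Internal helpers shared across modules.

# Derive a reproducible child seed for a named pipeline stage from a master
# seed, so toggling one stochastic stage does not perturb another's draws.
# Kept below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

# Evaluate an expression under a local RNG state; restores .Random.seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (x < lower || x > upper)
    stop("'", name, "' must be in [", lower, ", ", upper, "]", call. = FALSE)
  invisible(x)
}

check_prob <- function(x, name) check_scalar(x, name, 0, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a number for deterministic JSON/report output.
num <- function(x, digits = 6) round(as.numeric(x), digits)
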