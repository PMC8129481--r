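# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit
# so library code never clobbers a user's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Expand one user-facing seed into reproducible per-stage substreams, so a
# pipeline stage can be regenerated independently of the stages before it.
# Values stay below 2^31 - 1 (R integers are 32-bit).
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_("`%s` must be a single finite number", name)
  }
  if (strict_lower && x <= lower) stop_("`%s` must be > %s", name, lower)
  if (!strict_lower && x < lower) stop_("`%s` must be >= %s", name, lower)
  if (x > upper) stop_("`%s` must be <= %s", name, upper)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    stop_("`%s` must be an integer >= %d", name, min)
  }
  as.integer(x)
}

# row-wise variance of a numeric matrix (no NA expected)
row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}
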