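# internal helpers shared across the pipeline

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
# Generators take an explicit seed so no hidden global state leaks out.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (table-output convention; base round() is
# round-half-even).
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Pooled standard deviation across groups (weights = df per group).
# Groups with a single observation contribute no degrees of freedom;
# returns 0 when no group has df > 0.
pooled_sd <- function(values, groups) {
  groups <- as.character(groups)
  ss <- 0
  df <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    n <- length(v)
    if (n > 1L) {
      ss <- ss + sum((v - mean(v))^2)
      df <- df + (n - 1L)
    }
  }
  if (df == 0L) 0 else sqrt(ss / df)
}

stop_lk <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
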