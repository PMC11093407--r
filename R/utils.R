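# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministically derive `n` child seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clip01 <- function(x) pmin(1, pmax(0, x))

odds <- function(p) p / (1 - p)

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_config(field, sprintf("must lie in %s%g, %g%s",
                               if (strict_lower) "(" else "[", lower, upper,
                               if (strict_upper) ")" else "]"))
  }
  invisible(x)
}

check_interval <- function(x, field, lower = 0, upper = 1,
                           strict = FALSE) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] >= x[2]) {
    stop_config(field, "must be an increasing numeric interval c(lo, hi)")
  }
  ok <- if (strict) x[1] > lower && x[2] < upper else x[1] >= lower && x[2] <= upper
  if (!ok) {
    stop_config(field, sprintf("must be %s inside [%g, %g]",
                               if (strict) "strictly" else "contained", lower, upper))
  }
  invisible(x)
}

# Population z-score; errors on (near-)constant input so rank-deficient
# regressions fail loudly rather than silently producing NaN.
zscore <- function(x, label = "variable") {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps^0.5) {
    stop(sprintf("degenerate input: `%s` is constant, cannot z-score", label),
         call. = FALSE)
  }
  (x - mean(x)) / s
}
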