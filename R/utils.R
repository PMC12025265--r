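## Internal helpers shared across modules.

#' Clamp values into an interval
#'
#' @param x numeric vector, matrix or array.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the nearest bound;
#'   shape and dimensions preserved.
#' @examples
#' clamp(c(-0.2, 0.5, 1.3))
#' @export
clamp <- function(x, lo = 0, hi = 1) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. All stochastic operations in the package funnel
## through this so one global seed reproduces an experiment bit-for-bit.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

## Derive a stream of child seeds from one parent seed. Distinct streams get
## distinct, reproducible seeds below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, length(stream) >= 1L)
  (as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483629 + 1
}

## Validate a scalar numeric argument.
check_scalar <- function(x, name, lo = -Inf, hi = Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s.",
      name, if (strict) "(" else "[", format(lo), format(hi),
      if (strict) ")" else "]"
    ))
  }
  invisible(x)
}

check_raster <- function(x, name = "raster") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", name))
  }
  invisible(x)
}

same_shape <- function(a, b) identical(dim(a), dim(b))
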