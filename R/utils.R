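# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators (synthetic audio, sensor noise)
#' are reproducible without disturbing the caller's random stream.
#'
#' @param seed Integer seed (< 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Deterministic seed mixing; keeps results inside 32-bit integer range.
mix_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483629
  for (k in c(...)) {
    h <- (h * 69069 + as.numeric(k) + 1) %% 2147483629
  }
  as.integer(h)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
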