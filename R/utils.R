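#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not disturb the
#' caller's RNG stream. All stochastic operations in the package funnel
#' through this helper, which is what makes them bit-reproducible.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  code
}

# Derive a stream of child seeds from one parent seed, kept within 32-bit
# integer range. Used to give NMF replicates distinct but reproducible seeds.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Consistent validation error prefix so tests can match on the field name.
stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_invalid(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1, open_lo = TRUE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    stop_invalid(field, sprintf("must be in %s%g, %g%s",
                                if (open_lo) "(" else "[", lo, hi,
                                if (open_hi) ")" else "]"))
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
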