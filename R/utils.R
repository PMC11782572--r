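#' @keywords internal
#' @useDynLib exonscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Seed plumbing -----------------------------------------------------------

#' Derive a child seed from a master seed
#'
#' One global seed expands deterministically into per-module seeds via a
#' counter scheme, so independent reruns of single pipeline stages stay
#' reproducible. Derived seeds stay inside the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer counter identifying the consumer.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  m <- 2147483647            # 2^31 - 1, Mersenne prime used by Lehmer RNGs
  s <- (as.double(seed) %% m + m) %% m
  s <- (s * 48271 + as.double(offset) * 16807 + 1) %% m
  as.integer(s %% (m - 1) + 1)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# sample()'s scalar-x convenience is a footgun: these always treat x as the
# set of values to draw from, even at length 1.
sample_from <- function(x, n, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}

shuffle <- function(x) x[sample.int(length(x))]

# Validation helpers ------------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_range <- function(x, field, min = 1L) {
  if (length(x) != 2L || any(!is.finite(x)) || any(x < min) || x[1] > x[2]) {
    stop_field(field, sprintf(
      "must be a non-empty interval with lower bound >= %d", min))
  }
  as.integer(x)
}

check_unit <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop_field(field, "must be a single real in [0, 1]")
  }
  as.numeric(x)
}
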