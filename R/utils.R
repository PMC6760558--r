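#' @keywords internal
"_PACKAGE"

# Derive a sub-seed for an independent RNG stream from a master seed.
# Streams are indexed so that adding a new output artifact never perturbs
# the draws of existing ones. Kept below 2^31 - 1 (R integers are 32-bit).
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 7919 * stream) %% 2147483647)
}

# Evaluate `expr` under a seeded RNG stream, restoring the caller's RNG state.
with_stream <- function(seed, stream, expr) {
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
  set.seed(stream_seed(seed, stream))
  expr
}

# Stop with a message assembled from parts, without the call.
abort <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# First duplicated value in a vector, or NULL.
first_dup <- function(x) {
  d <- x[duplicated(x)]
  if (length(d)) d[[1L]] else NULL
}
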