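# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded operations behave
#' as pure functions of their inputs.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed from (master seed, subject index, stream index).
# Lehmer-style mixing; all intermediates stay below 2^53 so the arithmetic is
# exact in doubles, and the result is a valid 32-bit seed.
derive_seed <- function(master, subject = 0L, stream = 0L) {
  m <- 2147483647
  h <- (abs(as.numeric(master)) %% m) * 48271 %% m
  h <- (h + as.numeric(subject) * 7919 + as.numeric(stream) * 104729) %% m
  as.integer(h)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# row/column/slice index grids for a 3D array, as arrays of the same shape
coord_grids <- function(dims) {
  list(
    x = array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dim = dims),
    y = array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
              dim = dims),
    z = array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dim = dims)
  )
}
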