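# Internal helpers: seeding and small checks.

#' Derive a per-draw seed from a run seed and a counter
#'
#' Randomized template draws, per-model MSA subsamples and per-model
#' predictor noise all take their seed from `(run_seed, index)` so that any
#' single model of an ensemble can be regenerated without replaying the
#' whole run, and so that draws for different indices are independent
#' streams.
#'
#' @param seed integer run seed.
#' @param index nonnegative integer counter (draw or model index).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  # Weyl-style mixing; keeps the result a valid 32-bit R integer.
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 2654435761) %% 2147483647
  as.integer(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# scalar type guards
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
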