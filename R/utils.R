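#' @keywords internal
"_PACKAGE"

## Run an expression under a local RNG state. `seed = NULL` leaves the
## global stream untouched so callers can manage randomness themselves.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-subject substream: mix the subject index into the
## master seed, staying inside the 32-bit integer range.
subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 7919 + i * 104729) %% 2147483587) + 1L
}

stop_invalid <- function(...) stop(..., call. = FALSE)
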