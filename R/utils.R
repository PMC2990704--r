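# Independent RNG streams.
#
# The microsimulation separates natural-history randomness from screening
# randomness so that arms sharing a master seed share person-level disease
# trajectories (common random numbers): a strategy with zero adherence then
# reproduces the no-screening arm exactly, and paired strategy comparisons
# are free of between-arm sampling noise in the natural history.

make_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  e$state <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  e
}

stream_runif <- function(stream, n) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream$state, envir = globalenv())
  u <- stats::runif(n)
  stream$state <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  u
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

as_strategy_row <- function(strat) {
  if (is.data.frame(strat)) {
    if (nrow(strat) != 1) {
      stop("expected a single strategy row; got ", nrow(strat), call. = FALSE)
    }
    as.list(strat)
  } else {
    strat
  }
}
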