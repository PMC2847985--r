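# RNG plumbing: all stochastic operations take an explicit seed, run under a
# locally-set RNG state and restore the caller's state afterwards, so that one
# master seed fully determines every draw regardless of call order.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a child seed from a master seed by a counter scheme
#'
#' Children are produced by folding the master seed and a sequence of integer
#' counters (subject index, timepoint index, sequence index, ...) through a
#' multiplicative congruential hash modulo 2^31 - 1. The scheme is pure
#' arithmetic: the same master seed and counters always give the same child,
#' and children for different counters are decorrelated.
#'
#' @param master integer master seed.
#' @param ... integer counters (e.g. subject, timepoint, sequence).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (k in as.numeric(c(...))) {
    h <- (h * 48271 + k + 1) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
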