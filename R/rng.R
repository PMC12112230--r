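# Explicit RNG streams: every stochastic routine takes a stream object so no
# hidden global state leaks between the trainer, the sampler and user code.

#' Create a seeded random-number stream
#'
#' All stochastic functions in the package draw from an explicit stream rather
#' than the global generator, so runs are reproducible bit-for-bit from a
#' single integer seed and independent streams never interfere.
#'
#' @param seed Integer seed.
#' @return An object of class `fadm_rng`.
#' @examples
#' r <- rng_stream(1)
#' rng_norm(r, 3)
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- .swap_seed(NULL)
  set.seed(as.integer(seed))
  e$state <- .Random.seed
  .swap_seed(old)
  e$seed <- as.integer(seed)
  class(e) <- "fadm_rng"
  e
}

# install `state` as the global .Random.seed, returning the previous one
.swap_seed <- function(state) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  if (is.null(state)) {
    if (!is.null(old)) rm(".Random.seed", envir = genv)
  } else {
    assign(".Random.seed", state, envir = genv)
  }
  old
}

rng_eval <- function(rng, expr) {
  stopifnot(inherits(rng, "fadm_rng"))
  old <- .swap_seed(rng$state)
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    .swap_seed(old)
  })
  expr
}

#' @rdname rng_stream
#' @param rng A stream from [rng_stream()].
#' @param n Number of draws.
#' @export
rng_norm <- function(rng, n) rng_eval(rng, stats::rnorm(n))

#' @rdname rng_stream
#' @param max Upper bound (inclusive) for uniform integer draws.
#' @export
rng_int <- function(rng, n, max) rng_eval(rng, sample.int(max, n, replace = TRUE))

#' @rdname rng_stream
#' @export
rng_unif <- function(rng, n) rng_eval(rng, stats::runif(n))

# derive a child stream deterministically; keeps derived seeds < 2^31
rng_child <- function(rng, k) {
  rng_stream((as.double(rng$seed) * 48271 + k * 16807) %% 2147483647)
}
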