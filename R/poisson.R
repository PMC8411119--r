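#' A population of independent Poisson spike sources
#'
#' Spikes are drawn per time bin as independent Bernoulli events with
#' probability `rate * dt / 1000`, valid while `rate * dt` is well below
#' 1000 Hz*ms. With `rng_seed` set, the source carries a private RNG stream
#' so that repeated simulations reproduce identical spike trains regardless
#' of other randomness in the session.
#'
#' @param n Number of units.
#' @param rate Mean firing rate (Hz), `>= 0`.
#' @param rng_seed Optional integer seed for a private stream.
#' @return An object of class `poisson_source`.
#' @export
poisson_source <- function(n, rate, rng_seed = NULL) {
  stopifnot(n >= 1, rate >= 0)
  state <- new.env(parent = emptyenv())
  state$rng <- NULL
  if (!is.null(rng_seed)) {
    old <- .save_rng()
    set.seed(rng_seed)
    state$rng <- .Random.seed
    .restore_rng(old)
  }
  structure(list(size = as.integer(n), rate = rate,
                 rng_seed = rng_seed, state = state),
            class = "poisson_source")
}

#' @export
print.poisson_source <- function(x, ...) {
  cat(sprintf("<poisson_source> %d units at %g Hz%s\n", x$size, x$rate,
              if (is.null(x$rng_seed)) "" else sprintf(" (seed %d)", x$rng_seed)))
  invisible(x)
}

#' Draw one time bin of Poisson spikes
#'
#' @param src A [poisson_source()].
#' @param dt Bin width (ms).
#' @return Logical vector of length `src$size`.
#' @export
draw_poisson_spikes <- function(src, dt = 1) {
  stopifnot(inherits(src, "poisson_source"), dt > 0)
  if (src$rate == 0) return(rep(FALSE, src$size))
  p <- src$rate * dt / 1000
  if (is.null(src$state$rng)) return(runif(src$size) < p)
  old <- .save_rng()
  assign(".Random.seed", src$state$rng, envir = globalenv())
  out <- runif(src$size) < p
  src$state$rng <- .Random.seed
  .restore_rng(old)
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
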