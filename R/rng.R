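#' Independent seeded random-number sub-streams
#'
#' All randomized components of the package (arbitration, synthetic-cell
#' generation, PRNG-matrix search) draw from named sub-streams fanned out
#' from one master seed, so each component is reproducible in isolation and
#' no component perturbs another's stream or the user's global RNG state.
#'
#' @param seed integer master seed.
#' @param name character label of the component stream.
#' @return an integer seed < 2^31 deterministic in `(seed, name)`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(seed) * 2654435761 + h) %% 2147483629 + 1)
}

#' Create an isolated RNG stream
#'
#' Returns an environment holding its own Mersenne-Twister state; drawing
#' from it saves and restores the caller's `.Random.seed`, so streams never
#' interfere with each other or with user code.
#'
#' @param seed integer seed for this stream.
#' @return environment with functions `unif(n)`, `int(n, max)` (integers in
#'   `[1, max]`), and `sample_n(x, size)` (sample without replacement).
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  g <- globalenv()
  old <- if (exists(".Random.seed", envir = g, inherits = FALSE))
    get(".Random.seed", envir = g) else NULL
  set.seed(as.integer(seed %% 2147483647))
  e$state <- get(".Random.seed", envir = g)
  if (is.null(old)) rm(".Random.seed", envir = g)
  else assign(".Random.seed", old, envir = g)

  with_state <- function(fn) {
    old <- if (exists(".Random.seed", envir = g, inherits = FALSE))
      get(".Random.seed", envir = g) else NULL
    assign(".Random.seed", e$state, envir = g)
    on.exit({
      e$state <- get(".Random.seed", envir = g)
      if (is.null(old)) rm(".Random.seed", envir = g)
      else assign(".Random.seed", old, envir = g)
    })
    fn()
  }
  e$unif <- function(n = 1) with_state(function() stats::runif(n))
  e$int <- function(n, max) with_state(function() sample.int(max, n, replace = TRUE))
  e$sample_n <- function(x, size) with_state(function() {
    if (length(x) == 1) rep(x, min(size, 1)) else sample(x, size)
  })
  class(e) <- "rng_stream"
  e
}
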