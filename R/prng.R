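#' Composite hardware-style uniform PRNG
#'
#' The generator the uniform arbiter uses: a 32-bit state register advanced
#' as two concatenated 16-bit half-states. The fast half advances by the
#' full-cycle matrix `A0` every step; the slow half advances by `A1` once
#' each time a 16-bit step counter completes `2^16 - 1` steps, extending the
#' period to `(2^16 - 1)^2`. The output is `B %*% state` over GF(2), an
#' `m_out`-bit integer. (Which half is "fast" is a fixed convention here;
#' either choice yields the same period structure.)
#'
#' @param A0,A1 16x16 full-cycle transition matrices (generated with
#'   [generate_transition_matrix()] when omitted).
#' @param B `m_out x 32` output matrix (generated when omitted).
#' @param m_out output width in bits (default 9, enough to index 512 mRNAs).
#' @param seed0,seed1 nonzero 16-bit initial half-states.
#' @param seed master seed for matrix generation when matrices are omitted.
#' @return an environment of class `gf2_prng`.
#' @export
prng_new <- function(A0 = NULL, A1 = NULL, B = NULL, m_out = 9L,
                     seed0 = 1L, seed1 = 1L, seed = 1L) {
  rng <- rng_stream(derive_seed(seed, "prng-matrix-search"))
  if (is.null(A0)) A0 <- generate_transition_matrix(16L, rng = rng)
  if (is.null(A1)) A1 <- generate_transition_matrix(16L, rng = rng)
  if (is.null(B)) {
    # the slow half is frozen for 2^16 - 1 steps at a time, so outputs within
    # one epoch live in a coset of the fast half-block's column space: demand
    # full row rank on each 16-column half so every epoch is fully uniform
    for (tries in 1:10000) {
      B <- generate_output_matrix(m_out, 32L, rng = rng)
      if (m_out > 16) break
      if (gf2_rank(B[, 1:16, drop = FALSE]) == m_out &&
          gf2_rank(B[, 17:32, drop = FALSE]) == m_out) break
      if (tries == 10000) stop("no half-block full-rank output matrix found")
    }
  }
  stopifnot(nrow(A0) == 16, nrow(A1) == 16, ncol(B) == 32, nrow(B) == m_out)
  if (seed0 < 1 || seed0 > 65535 || seed1 < 1 || seed1 > 65535) {
    stop("half-state seeds must be nonzero 16-bit integers")
  }
  p <- new.env(parent = emptyenv())
  p$A0 <- A0; p$A1 <- A1; p$B <- B
  p$m_out <- as.integer(m_out)
  p$x0 <- as.integer(seed0)
  p$x1 <- as.integer(seed1)
  p$counter <- 0L
  p$masks0 <- .gf2_row_masks(A0)
  p$masks1 <- .gf2_row_masks(A1)
  # split B into masks over the two 16-bit halves (state = [x0, x1])
  p$bmask0 <- .gf2_row_masks(B[, 1:16, drop = FALSE])
  p$bmask1 <- .gf2_row_masks(B[, 17:32, drop = FALSE])
  p$pow2_16 <- as.integer(2^(0:15))
  p$pow2_out <- as.integer(2^(0:(m_out - 1)))
  class(p) <- c("gf2_prng", "environment")
  p
}

#' Advance the composite generator one step
#'
#' @param p a [prng_new()] object (mutated in place).
#' @return the `m_out`-bit output integer in `[0, 2^m_out)`.
#' @export
prng_step <- function(p) {
  parity <- .parity16()
  p$x0 <- sum(p$pow2_16[parity[bitwAnd(p$masks0, p$x0) + 1L] == 1L])
  p$counter <- p$counter + 1L
  if (p$counter == 65535L) {
    p$x1 <- sum(p$pow2_16[parity[bitwAnd(p$masks1, p$x1) + 1L] == 1L])
    p$counter <- 0L
  }
  out_bits <- bitwXor(parity[bitwAnd(p$bmask0, p$x0) + 1L],
                      parity[bitwAnd(p$bmask1, p$x1) + 1L])
  sum(p$pow2_out[out_bits == 1L])
}

#' Draw a uniform index in \[1, M\] from the composite generator
#'
#' Rejection sampling: outputs `>= M` are discarded, so the returned index
#' is exactly uniform (a hardware implementation would more likely truncate;
#' exact uniformity is the property the arbiter needs).
#'
#' @param p a [prng_new()] object.
#' @param M number of endpoints; requires `2^m_out >= M`.
#' @return integer in `[1, M]` (1-based).
#' @export
prng_draw_index <- function(p, M) {
  if (2^p$m_out < M) stop("M exceeds the generator's output range")
  repeat {
    o <- prng_step(p)
    if (o < M) return(o + 1L)
  }
}

#' Draw many indices
#'
#' @inheritParams prng_draw_index
#' @param n number of draws.
#' @return integer vector in `[1, M]`.
#' @export
prng_draw_indices <- function(p, M, n) {
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- prng_draw_index(p, M)
  out
}

#' Chi-square uniformity test for index samples
#'
#' Pearson goodness-of-fit of observed index counts against the uniform
#' distribution on `M` bins, with `M - 1` degrees of freedom.
#'
#' @param samples integer indices in `[0, M)` (0-based) or `[1, M]`
#'   (1-based); `one_based` says which.
#' @param M number of bins.
#' @param one_based whether samples are 1-based (default: autodetect from
#'   the range).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
uniformity_chi_square <- function(samples, M, one_based = any(samples == M)) {
  if (length(samples) < 5 * M) {
    stop("need at least 5*M samples for a stable chi-square test")
  }
  idx <- if (one_based) samples else samples + 1L
  counts <- tabulate(as.integer(idx), nbins = M)
  expected <- length(samples) / M
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, df = M - 1,
       p_value = stats::pchisq(stat, df = M - 1, lower.tail = FALSE))
}
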