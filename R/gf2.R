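#' GF(2) matrix utilities
#'
#' Binary matrices over GF(2) drive the hardware-style pseudorandom number
#' generator: a transition matrix `A` advances a state register
#' (`x_{i+1} = A x_i` over GF(2)) and an output matrix `B` projects the state
#' onto the output bits. A transition matrix is *full-cycle* when the
#' recurrence visits all `2^n - 1` nonzero states before repeating, i.e. the
#' multiplicative order of `A` is `2^n - 1`.
#'
#' @name gf2
NULL

gf2_identity <- function(n) diag(1L, n)

#' @rdname gf2
#' @param A,B 0/1 matrices.
#' @return `gf2_multiply`: the GF(2) matrix product.
#' @export
gf2_multiply <- function(A, B) (A %*% B) %% 2L

#' @rdname gf2
#' @param e non-negative exponent (may exceed 2^31; doubles are exact here).
#' @return `gf2_pow`: `A^e` over GF(2) by square-and-multiply.
#' @export
gf2_pow <- function(A, e) {
  stopifnot(nrow(A) == ncol(A), e >= 0)
  acc <- gf2_identity(nrow(A))
  P <- A
  while (e > 0) {
    if (e %% 2 == 1) acc <- gf2_multiply(acc, P)
    P <- gf2_multiply(P, P)
    e <- e %/% 2
  }
  acc
}

#' @rdname gf2
#' @param M a 0/1 matrix.
#' @return `gf2_rank`: the rank over GF(2) (Gaussian elimination).
#' @export
gf2_rank <- function(M) {
  M <- M %% 2L
  r <- 0L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[, col] == 1L & seq_len(nrow(M)) > r)
    if (!length(piv)) next
    r <- r + 1L
    if (piv[1] != r) M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
    hit <- which(M[, col] == 1L & seq_len(nrow(M)) != r)
    if (length(hit)) M[hit, ] <- (M[hit, , drop = FALSE] +
                                  rep(M[r, ], each = length(hit))) %% 2L
    if (r == nrow(M)) break
  }
  r
}

# prime factors (distinct) of m by trial division; m <= 2^53 exact in doubles
.prime_factors <- function(m) {
  f <- numeric(0)
  d <- 2
  while (d * d <= m) {
    if (m %% d == 0) {
      f <- c(f, d)
      while (m %% d == 0) m <- m / d
    }
    d <- d + 1
  }
  if (m > 1) f <- c(f, m)
  f
}

# packed-integer state stepping: rows of A as bitmasks, 16-bit parity table
.gf2_row_masks <- function(A) {
  n <- ncol(A)
  pow2 <- 2^(0:(n - 1))
  as.integer(A %*% pow2)
}
.parity16 <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      p <- integer(65536)
      v <- 0:65535
      for (b in 0:15) p <- bitwXor(p, bitwAnd(bitwShiftR(v, b), 1L))
      tab <<- p
    }
    tab
  }
})
# one recurrence step on a packed state (n <= 16)
.gf2_step_packed <- function(masks, x, pow2, parity) {
  sum(pow2[parity[bitwAnd(masks, x) + 1L] == 1L])
}

#' Orbit length of the state recurrence from a given start
#'
#' Iterates `x -> A x` over GF(2) from `start` until the start state recurs,
#' up to `2^n` steps. For an invertible `A` the orbit is a pure cycle, so
#' the returned count is the cycle length through `start`.
#'
#' @param A square 0/1 transition matrix with `n <= 20` rows.
#' @param start packed nonzero start state (integer in `[1, 2^n)`); default 1.
#' @return orbit length, or `NA` if the start does not recur within `2^n`
#'   steps (singular matrix).
#' @export
gf2_orbit_length <- function(A, start = 1L) {
  n <- nrow(A)
  stopifnot(n <= 20, start >= 1, start < 2^n)
  masks <- .gf2_row_masks(A)
  pow2 <- as.integer(2^(0:(n - 1)))
  parity <- .parity16()
  if (n > 16) {
    # split parity over two half-words
    par <- function(z) bitwXor(parity[bitwAnd(z, 65535L) + 1L],
                               parity[bitwShiftR(z, 16L) + 1L])
    step <- function(x) sum(pow2[par(bitwAnd(masks, x)) == 1L])
  } else {
    step <- function(x) sum(pow2[parity[bitwAnd(masks, x) + 1L] == 1L])
  }
  x <- step(as.integer(start))
  k <- 1
  lim <- 2^n
  while (x != start) {
    x <- step(x)
    k <- k + 1
    if (k > lim) return(NA_real_)
  }
  k
}

#' Full-cycle test for a GF(2) transition matrix
#'
#' `TRUE` iff the multiplicative order of `A` is `2^n - 1`. Two verification
#' routes are implemented: `"enumerate"` walks the whole state orbit (exact,
#' n <= 20); `"order"` checks `A^(2^n - 1) = I` together with
#' `A^((2^n - 1)/p) != I` for every prime factor `p` of `2^n - 1`
#' (square-and-multiply; any n). `"auto"` picks `"order"` for speed.
#'
#' @param A square 0/1 matrix, no all-zero column.
#' @param method `"auto"`, `"enumerate"`, or `"order"`.
#' @return logical.
#' @export
is_full_cycle <- function(A, method = c("auto", "enumerate", "order")) {
  method <- match.arg(method)
  stopifnot(nrow(A) == ncol(A))
  if (any(colSums(A) == 0)) stop("transition matrix has an all-zero column")
  n <- nrow(A)
  if (method == "auto") method <- "order"
  if (method == "enumerate") {
    if (n > 20) stop("enumeration limited to n <= 20; use method = 'order'")
    len <- gf2_orbit_length(A, 1L)
    return(!is.na(len) && len == 2^n - 1)
  }
  m <- 2^n - 1
  I <- gf2_identity(n)
  if (!all(gf2_pow(A, m) == I)) return(FALSE)
  for (p in .prime_factors(m)) {
    if (all(gf2_pow(A, m / p) == I)) return(FALSE)
  }
  TRUE
}

#' Generate a full-cycle transition matrix
#'
#' Rejection search: each row receives `k` ones at random positions with `k`
#' drawn from `ones_range` (the 4-6 range keeps a hardware row computable in
#' one 6-input LUT); a candidate is rejected if any column is all-zero (a
#' state bit that would not affect the next state) or if it is not
#' full-cycle. For `n < 8` the default range is relaxed to `c(1, min(6, n))`
#' — with rows this dense no full-cycle matrix exists at small n.
#'
#' @param n state width in bits (>= 2).
#' @param ones_range integer length-2: allowed ones per row.
#' @param rng an [rng_stream()]; defaults to a fresh stream with `seed`.
#' @param seed used only when `rng` is NULL.
#' @param max_tries rejection budget.
#' @return an `n x n` 0/1 matrix with attribute `tries`.
#' @export
generate_transition_matrix <- function(n, ones_range = NULL, rng = NULL,
                                       seed = 1L, max_tries = 10000L) {
  stopifnot(n >= 2)
  if (is.null(ones_range)) {
    ones_range <- if (n >= 8) c(4L, 6L) else c(1L, min(6L, n))
  }
  lo <- max(1L, ones_range[1]); hi <- min(n, ones_range[2])
  stopifnot(lo <= hi)
  if (is.null(rng)) rng <- rng_stream(derive_seed(seed, "prng-matrix-search"))
  for (tries in seq_len(max_tries)) {
    A <- matrix(0L, n, n)
    for (i in seq_len(n)) {
      k <- if (lo == hi) lo else lo + rng$int(1, hi - lo + 1L) - 1L
      A[i, rng$sample_n(seq_len(n), k)] <- 1L
    }
    if (any(colSums(A) == 0)) next
    if (is_full_cycle(A, "order")) {
      attr(A, "tries") <- tries
      return(A)
    }
  }
  stop("no full-cycle matrix found in ", max_tries, " tries (n = ", n,
       ", ones per row in [", lo, ", ", hi, "])")
}

#' Generate an output (projection) matrix
#'
#' An `m_out x n` 0/1 matrix with at most 6 ones per row, no all-zero row,
#' and full row rank over GF(2) — rank `m_out` makes the projection
#' surjective onto all `2^m_out` outputs over the full nonzero-state cycle
#' (every output pattern has nonzero preimages when `m_out < n`).
#'
#' @param m_out output width in bits (`1 <= m_out <= n`).
#' @inheritParams generate_transition_matrix
#' @return an `m_out x n` 0/1 matrix.
#' @export
generate_output_matrix <- function(m_out, n, ones_range = c(4L, 6L),
                                   rng = NULL, seed = 1L, max_tries = 10000L) {
  stopifnot(m_out >= 1, m_out <= n)
  lo <- max(1L, min(ones_range[1], n)); hi <- min(n, ones_range[2])
  if (is.null(rng)) rng <- rng_stream(derive_seed(seed, "prng-matrix-search"))
  for (tries in seq_len(max_tries)) {
    B <- matrix(0L, m_out, n)
    for (i in seq_len(m_out)) {
      k <- if (lo == hi) lo else lo + rng$int(1, hi - lo + 1L) - 1L
      B[i, rng$sample_n(seq_len(n), k)] <- 1L
    }
    if (any(rowSums(B) == 0)) next
    if (gf2_rank(B) == m_out) {
      attr(B, "tries") <- tries
      return(B)
    }
  }
  stop("no full-rank output matrix found in ", max_tries, " tries")
}

#' Read/write GF(2) matrices as plain-text 0/1 grids
#'
#' @param M 0/1 matrix.
#' @param path file path.
#' @export
write_gf2_matrix <- function(M, path) {
  writeLines(apply(M, 1, paste0, collapse = ""), path)
}

#' @rdname write_gf2_matrix
#' @return `read_gf2_matrix`: an integer 0/1 matrix.
#' @export
read_gf2_matrix <- function(path) {
  rows <- readLines(path)
  M <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  if (any(is.na(M)) || any(M > 1)) stop("not a 0/1 grid: ", path)
  M
}
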