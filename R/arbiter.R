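#' Ribosome-grant arbitration policies
#'
#' The arbiter decides which requesting mRNA receives a freed ribosome.
#' Two policies are provided:
#' \describe{
#'   \item{round_robin}{deterministic: scans mRNA indices cyclically from an
#'     internal pointer, granting each requesting mRNA until ribosomes or
#'     requests run out; the pointer advances past the last grant. Biased:
#'     when most mRNAs are free to receive, the mRNA following the releasing
#'     one tends to collect the ribosome.}
#'   \item{uniform}{random. In `mode = "event"` each grant is drawn uniformly
#'     among the current requesters without replacement (used by the
#'     event-driven engine). In `mode = "cycle"` one index is drawn per clock
#'     cycle regardless of the state of the indexed mRNA, and a miss grants
#'     nothing that cycle (the hardware draw-and-retry semantics, used by the
#'     fixed-step oracle).}
#' }
#' The uniform policy draws either from a seeded software stream or from a
#' composite GF(2) generator built with [prng_new()].
#'
#' @param policy `"round_robin"` or `"uniform"`.
#' @param M number of mRNA endpoints.
#' @param seed integer seed for the uniform policy's stream (ignored for
#'   round-robin).
#' @param mode `"event"` or `"cycle"` (uniform policy only).
#' @param prng optional `gf2_prng` object to use as the draw source instead
#'   of the software stream (requires `2^m_out >= M`).
#' @return an environment of class `arbiter` with internal state; pass it to
#'   the simulation engines or to [arbiter_select()].
#' @export
make_arbiter <- function(policy = c("round_robin", "uniform"), M,
                         seed = 1L, mode = c("event", "cycle"), prng = NULL) {
  policy <- match.arg(policy)
  mode <- match.arg(mode)
  a <- new.env(parent = emptyenv())
  a$policy <- policy
  a$M <- as.integer(M)
  a$mode <- mode
  a$pointer <- 1L
  if (policy == "uniform") {
    if (!is.null(prng)) {
      if (2^prng$m_out < M) stop("PRNG output width too small for M endpoints")
      a$draw <- function(k) prng_draw_index(prng, k)
    } else {
      s <- rng_stream(seed)
      a$draw <- function(k) s$int(1, k)
    }
  }
  class(a) <- c("arbiter", "environment")
  a
}

#' Select grants under the arbiter's policy
#'
#' Dispatches to [round_robin_select()] or [uniform_select()] and mutates the
#' arbiter state in place. Grants never exceed the number of free ribosomes;
#' in event mode granted indices are a subset of the requests.
#'
#' @param arb an [make_arbiter()] object.
#' @param requests integer vector of requesting mRNA indices (1-based).
#' @param free number of free ribosomes.
#' @return ordered integer vector of granted mRNA indices (possibly empty).
#' @export
arbiter_select <- function(arb, requests, free) {
  if (arb$policy == "round_robin") round_robin_select(requests, free, arb)
  else uniform_select(requests, free, arb, arb$mode)
}

#' Round-robin grant selection
#'
#' @inheritParams arbiter_select
#' @param state an `arbiter` whose pointer is advanced past the last grant.
#' @return ordered granted indices.
#' @export
round_robin_select <- function(requests, free, state) {
  stopifnot(free >= 0)
  if (free == 0 || length(requests) == 0) return(integer(0))
  M <- state$M
  scan <- ((state$pointer - 1L + 0:(M - 1L)) %% M) + 1L
  hits <- scan[scan %in% requests]
  granted <- hits[seq_len(min(free, length(hits)))]
  if (length(granted)) state$pointer <- granted[length(granted)] %% M + 1L
  granted
}

#' Uniform grant selection
#'
#' @inheritParams arbiter_select
#' @param state an `arbiter` carrying the draw source.
#' @param mode `"event"`: grants drawn uniformly among requesters without
#'   replacement; `"cycle"`: a single index drawn regardless of mRNA state,
#'   granting only on a hit.
#' @return ordered granted indices.
#' @export
uniform_select <- function(requests, free, state, mode = c("event", "cycle")) {
  mode <- match.arg(mode)
  stopifnot(free >= 0)
  if (mode == "cycle") {
    j <- state$draw(state$M)
    if (free > 0 && j %in% requests) return(j) else return(integer(0))
  }
  if (free == 0 || length(requests) == 0) return(integer(0))
  k <- min(free, length(requests))
  remaining <- as.integer(requests)
  granted <- integer(k)
  for (g in seq_len(k)) {
    pick <- state$draw(length(remaining))
    granted[g] <- remaining[pick]
    remaining <- remaining[-pick]
  }
  granted
}

#' Successor-grant (neighbor) bias of a grant sequence
#'
#' Fraction of consecutive grant pairs in which the successor index
#' `i + 1 (mod M)` receives the next grant. An unbiased policy gives about
#' `1/M`; the round-robin arbiter in the all-free regime gives values far
#' above that.
#'
#' @param grant_seq integer vector of granted mRNA indices (1-based), length
#'   >= 2.
#' @param M number of mRNA endpoints.
#' @return fraction in `[0, 1]`.
#' @export
neighbor_bias <- function(grant_seq, M) {
  stopifnot(length(grant_seq) >= 2)
  cur <- grant_seq[-length(grant_seq)]
  nxt <- grant_seq[-1]
  mean(nxt == (cur %% M) + 1L)
}

#' Bernoulli window for the uniform arbiter
#'
#' Smallest number of draws `W` such that the probability of seeing fewer
#' than two successes in `W` independent Bernoulli(1/m) trials is below
#' `p_error`, computed by exact binomial tail evaluation. This is the window
#' within which the uniform arbiter returns to a given mRNA twice with high
#' probability, and hence the horizon over which its pending-release counter
#' must not overflow.
#'
#' @param m number of endpoints (>= 1).
#' @param p_error acceptable miss probability, in (0, 1).
#' @return integer window length `W >= 2`.
#' @export
bernoulli_window <- function(m, p_error) {
  stopifnot(m >= 1, p_error > 0, p_error < 1)
  W <- 2L
  while (stats::pbinom(1, W, 1 / m) >= p_error) W <- W + 1L
  W
}

#' Pending-release counter sizing
#'
#' During one arbiter revisit window of `W` ticks, successive terminations on
#' one mRNA are separated by at least `D * d_minimal` ticks (the trailing
#' ribosome must advance `D` codons, each taking at least the minimal codon
#' delay), so at most `floor(W / (D * d_minimal)) + 1` release events can
#' accumulate. The counter must hold that count, hence
#' `ceil(log2(max_releases + 1))` bits. For the round-robin arbiter the
#' window is exactly `m` ticks; for the uniform arbiter use
#' [bernoulli_window()].
#'
#' @param W window length in ticks.
#' @param D ribosome footprint in codons.
#' @param d_minimal minimal per-codon delay in ticks (>= 1).
#' @return list with `max_releases` and `bits`.
#' @export
release_counter_bits <- function(W, D, d_minimal) {
  stopifnot(W >= 1, D >= 1, d_minimal >= 1)
  max_releases <- W %/% (D * d_minimal) + 1
  list(max_releases = max_releases,
       bits = as.integer(ceiling(log2(max_releases + 1))))
}

#' Benchmark an arbiter on always-requesting endpoints
#'
#' Repeatedly offers all `M` endpoints as requesters with one free ribosome
#' per call and records the grant sequence — the all-free regime in which the
#' round-robin successor bias is maximal and the uniform policy should be
#' indistinguishable from iid uniform draws.
#'
#' @param arb an [make_arbiter()] object.
#' @param n_grants number of grants to collect.
#' @return list with `grant_seq`, per-endpoint `counts`, `neighbor_bias`,
#'   and `chisq` (the [uniformity_chi_square()] report).
#' @export
arbiter_bench <- function(arb, n_grants) {
  M <- arb$M
  seq_out <- integer(n_grants)
  got <- 0L
  all_req <- seq_len(M)
  while (got < n_grants) {
    g <- arbiter_select(arb, all_req, 1L)
    if (length(g)) {
      got <- got + 1L
      seq_out[got] <- g[1]
    }
  }
  counts <- tabulate(seq_out, nbins = M)
  list(grant_seq = seq_out, counts = counts,
       neighbor_bias = neighbor_bias(seq_out, M),
       chisq = uniformity_chi_square(seq_out, M, one_based = TRUE))
}
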