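#' Time-event vector of one ribosome on one mRNA
#'
#' Given the grant time of a new ribosome and the time-event vector of the
#' previous ribosome on the same mRNA, computes the absolute completion time
#' of initiation, of every codon, and of release. Initiation completes at
#' `grant + init_delay`. Codon `k` (1-based) starts at the later of the own
#' previous step's completion and — while `k + D <= L` — the previous
#' ribosome's completion of codon `k + D` (footprint exclusion: the site
#' ahead must clear before elongation proceeds); the last `D` codons carry no
#' blocking term. A protein is attributed at the last codon's completion
#' (termination); release to the pool follows after the diffusion delay.
#'
#' The mRNA may request its next ribosome once this ribosome clears the 5'
#' footprint, i.e. at the completion of codon `min(D + 1, L)`; that time is
#' returned as `gate` and enforced as a precondition on the next grant.
#'
#' @param mrna an mRNA instance (an [mrna_spec()], or a cell instance).
#' @param prev the previous ribosome's `time_event_vector`, or `NULL` for
#'   the first ribosome.
#' @param grant_time tick at which the ribosome is granted (>= 0, and >= the
#'   previous ribosome's `gate`).
#' @param D ribosome footprint in codons.
#' @return object of class `time_event_vector`: list with `grant`,
#'   `init_done`, `codon_done` (numeric length `L`), `protein_time`,
#'   `release`, `gate`.
#' @export
compute_time_event_vector <- function(mrna, prev, grant_time, D) {
  L <- length(mrna$codons)
  stopifnot(grant_time >= 0, D >= 1)
  if (!is.null(prev) && grant_time < prev$gate) {
    stop("grant at ", grant_time, " precedes footprint clearance at ",
         prev$gate, " (scheduler bug)")
  }
  delays <- mrna$delays
  codon_done <- numeric(L)
  t_prev <- grant_time + mrna$init_delay
  init_done <- t_prev
  n_blocked <- max(0L, L - D)   # codons 1..L-D carry a blocking term
  for (k in seq_len(L)) {
    start <- if (k <= n_blocked && !is.null(prev))
      max(t_prev, prev$codon_done[k + D]) else t_prev
    t_prev <- start + delays[k]
    codon_done[k] <- t_prev
  }
  structure(list(
    grant = grant_time, init_done = init_done, codon_done = codon_done,
    protein_time = codon_done[L],
    release = codon_done[L] + mrna$diff_delay,
    gate = codon_done[min(D + 1L, L)]
  ), class = "time_event_vector")
}

# growable numeric/integer buffer: push in amortized O(1)
.buf_new <- function(mode = "numeric", init = 256L) {
  b <- new.env(parent = emptyenv())
  b$v <- vector(mode, init)
  b$n <- 0L
  b
}
.buf_push <- function(b, x) {
  need <- b$n + length(x)
  if (need > length(b$v)) {
    nv <- vector(mode(b$v), max(2L * length(b$v), need))
    nv[seq_len(b$n)] <- b$v[seq_len(b$n)]
    b$v <- nv
  }
  b$v[(b$n + 1L):need] <- x
  b$n <- need
  invisible(b)
}
.buf_get <- function(b) b$v[seq_len(b$n)]

#' Event-driven whole-cell translation simulation
#'
#' Implements the global scheduler loop: ribosomes released at or before the
#' current time return to the pool; if no ribosome is free, time jumps to
#' the earliest release; requesting mRNAs (those whose previous ribosome has
#' cleared the 5' footprint — the first ribosome is requested at tick 0) are
#' then served by the arbitration policy; granted mRNAs recompute their
#' time-event vectors; if nobody requests at the current time, time jumps to
#' the earliest request. Within a tick, releases are processed before
#' requests, so a ribosome freed at `t` can be granted at `t`. The loop runs
#' until the current time reaches the horizon; protein events at or before
#' the horizon are counted.
#'
#' @param cell a [cell()] object.
#' @param horizon simulation horizon in ticks (>= 1).
#' @param policy `"round_robin"`, `"uniform"`, or a prebuilt
#'   [make_arbiter()] object (must be event-mode).
#' @param seed integer seed for stochastic policies (via the `"arbitration"`
#'   sub-stream of [derive_seed()]).
#' @return object of class `sim_result`; see [summarize_result()].
#' @export
run_event_driven <- function(cell, horizon, policy = "round_robin", seed = 1L) {
  stopifnot(inherits(cell, "ribocell"), horizon >= 1)
  M <- length(cell$instances)
  D <- cell$D
  R <- cell$R
  ids <- vapply(cell$instances, `[[`, "", "id")
  arb <- if (inherits(policy, "arbiter")) policy
    else make_arbiter(policy, M, seed = derive_seed(seed, "arbitration"))
  if (arb$policy == "uniform" && arb$mode == "cycle") {
    stop("the event-driven engine requires an event-mode arbiter; ",
         "cycle-mode semantics are tick-based (use run_fixed_step_oracle)")
  }

  next_request <- numeric(M)          # first ribosome requested at tick 0
  last_tev <- vector("list", M)
  proteins <- integer(M)
  grants <- integer(M)
  active <- integer(M)
  max_active <- integer(M)
  pend_pt <- numeric(0); pend_pi <- integer(0)   # pending protein events
  pend_rel <- numeric(0)                         # pending pool returns
  prot_t <- .buf_new(); prot_i <- .buf_new("integer")
  gseq <- .buf_new("integer"); gsize <- .buf_new("integer")
  g_time <- .buf_new(); rel_all <- .buf_new()
  tr_t <- .buf_new(); tr_free <- .buf_new("integer")
  tr_req <- .buf_new("integer"); tr_act <- .buf_new("integer")
  tr_dif <- .buf_new("integer")
  it_t <- .buf_new(); it_max <- .buf_new("integer")

  free <- R
  now <- 0
  iterations <- 0L

  absorb <- function(upto) {
    if (length(pend_rel)) {
      hit <- pend_rel <= upto
      if (any(hit)) {
        free <<- free + sum(hit)
        pend_rel <<- pend_rel[!hit]
      }
    }
    if (length(pend_pt)) {
      hit <- pend_pt <= upto
      if (any(hit)) {
        done_i <- pend_pi[hit]
        for (i in done_i) {
          proteins[i] <<- proteins[i] + 1L
          active[i] <<- active[i] - 1L
        }
        .buf_push(prot_t, pend_pt[hit]); .buf_push(prot_i, done_i)
        pend_pt <<- pend_pt[!hit]; pend_pi <<- pend_pi[!hit]
      }
    }
  }

  while (now < horizon) {
    absorb(now)
    iterations <- iterations + 1L
    .buf_push(it_t, now); .buf_push(it_max, max(active, 0L))
    req <- which(next_request <= now)
    .buf_push(tr_t, now); .buf_push(tr_free, free)
    .buf_push(tr_req, length(req)); .buf_push(tr_act, sum(active))
    .buf_push(tr_dif, length(pend_rel) - sum(active))
    if (free == 0L) {
      if (!length(pend_rel)) break      # R == 0, or everything stuck: done
      now <- min(pend_rel)
      next
    }
    if (!length(req)) {
      now <- min(next_request)
      next
    }
    g <- arbiter_select(arb, req, free)
    if (length(g)) {
      for (j in g) {
        tev <- compute_time_event_vector(cell$instances[[j]], last_tev[[j]], now, D)
        last_tev[[j]] <- tev
        grants[j] <- grants[j] + 1L
        active[j] <- active[j] + 1L
        if (active[j] > max_active[j]) max_active[j] <- active[j]
        next_request[j] <- tev$gate
        pend_pt <- c(pend_pt, tev$protein_time)
        pend_pi <- c(pend_pi, j)
        pend_rel <- c(pend_rel, tev$release)
        .buf_push(g_time, now)
        .buf_push(rel_all, tev$release)
      }
      free <- free - length(g)
      .buf_push(gseq, g)
      .buf_push(gsize, length(g))
      # re-record the state at this instant so the step-function trajectory
      # reflects the post-grant pool (the later duplicate wins)
      .buf_push(tr_t, now); .buf_push(tr_free, free)
      .buf_push(tr_req, length(req) - length(g)); .buf_push(tr_act, sum(active))
      .buf_push(tr_dif, length(pend_rel) - sum(active))
    }
  }
  absorb(horizon)

  pt <- .buf_get(prot_t); pi <- .buf_get(prot_i)
  protein_times <- split(pt, factor(pi, levels = seq_len(M)))
  names(protein_times) <- ids
  # exact free-pool step function from the grant/return event times (the
  # iteration trajectory only samples scheduler wake-ups and misses returns
  # that fall inside a jump)
  rel <- .buf_get(rel_all); rel <- rel[rel <= horizon]
  gt <- .buf_get(g_time)
  ev_t <- c(gt, rel)
  ev_d <- c(rep(-1L, length(gt)), rep(1L, length(rel)))
  ord <- order(ev_t, -ev_d)          # returns before grants at equal times
  pool <- data.frame(time = c(0, ev_t[ord]),
                     free = R + cumsum(c(0L, ev_d[ord])))
  structure(list(
    engine = "event", policy = arb$policy, seed = seed,
    horizon = horizon, delta_t = cell$delta_t, R = R, D = D, ids = ids,
    proteins = stats::setNames(proteins, ids),
    protein_times = protein_times,
    grants = stats::setNames(grants, ids),
    grant_seq = .buf_get(gseq),
    grant_sizes = .buf_get(gsize),
    max_active = stats::setNames(max_active, ids),
    trajectory = data.frame(
      time = .buf_get(tr_t), free = .buf_get(tr_free),
      free_mrnas = .buf_get(tr_req), active = .buf_get(tr_act),
      diffusing = .buf_get(tr_dif)
    ),
    pool = pool,
    iter_time = .buf_get(it_t), iter_max_active = .buf_get(it_max),
    iterations = iterations,
    final_free = free
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", x$engine, "engine,", x$policy, "policy, horizon",
      x$horizon, "ticks\n")
  cat("  proteins:", sum(x$proteins), " grants:", sum(x$grants),
      " iterations:", x$iterations, " free at end:", x$final_free, "\n")
  invisible(x)
}
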