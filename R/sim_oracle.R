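#' Fixed-step (tick-by-tick) translation simulation
#'
#' Brute-force reference engine mirroring the hardware semantics: every
#' delay is a countdown timer decremented once per tick. Each active
#' ribosome holds its current codon and remaining time; it advances to the
#' next codon only when the ribosome ahead has cleared the footprint
#' (positional gap of at least `D` codons at every tick), terminates at the
#' last codon's completion (one protein), counts down the diffusion delay
#' off the mRNA, and then returns to the pool. An mRNA requests a new
#' ribosome when it is empty or its youngest ribosome has cleared the 5'
#' footprint (completed codon `min(D + 1, L)`); the first request is at tick
#' 0. Within a tick: movements and terminations are processed 3'-to-5'
#' (leading ribosome first), then pool returns, then requests and grants —
#' so a ribosome freed at `t` can be granted at `t`, as in the event-driven
#' engine.
#'
#' With a deterministic policy, or a stochastic policy sharing its decision
#' stream, this engine reproduces the protein counts and protein event times
#' of [run_event_driven()] exactly; it exists as an independent oracle and
#' for the hardware cycle-mode arbiter semantics.
#'
#' @inheritParams run_event_driven
#' @param audit_gaps if `TRUE` (default), track the minimal positional gap
#'   between co-resident ribosomes over the whole run (reported as
#'   `min_gap`; must be `>= D`).
#' @return object of class `sim_result` (same observable fields as the
#'   event-driven engine; `trajectory` has one row per tick).
#' @export
run_fixed_step_oracle <- function(cell, horizon, policy = "round_robin",
                                  seed = 1L, audit_gaps = TRUE) {
  stopifnot(inherits(cell, "ribocell"), horizon >= 1)
  M <- length(cell$instances)
  D <- cell$D
  R <- cell$R
  ids <- vapply(cell$instances, `[[`, "", "id")
  arb <- if (inherits(policy, "arbiter")) policy
    else make_arbiter(policy, M, seed = derive_seed(seed, "arbitration"))
  cycle_mode <- arb$policy == "uniform" && arb$mode == "cycle"

  L <- vapply(cell$instances, function(i) length(i$codons), 0L)
  delays <- lapply(cell$instances, `[[`, "delays")
  init_d <- vapply(cell$instances, `[[`, 0L, "init_delay")
  diff_d <- vapply(cell$instances, `[[`, 0L, "diff_delay")
  gate_codon <- pmin(D + 1L, L)

  # per-instance ribosome queues, leading (oldest) first
  # phase: 0 = initiating, 1 = translating codon done+1, 2 = waiting to enter
  q_phase <- lapply(seq_len(M), function(i) integer(0))
  q_done <- q_phase
  q_rem <- q_phase

  proteins <- integer(M)
  grants <- integer(M)
  max_active <- integer(M)
  pend_rel <- numeric(0)
  prot_t <- .buf_new(); prot_i <- .buf_new("integer")
  gseq <- .buf_new("integer"); gsize <- .buf_new("integer")
  free <- R
  min_gap <- Inf
  ticks <- horizon + 1L
  tr_free <- integer(ticks); tr_req <- integer(ticks)
  tr_act <- integer(ticks); tr_dif <- integer(ticks)
  it_max <- integer(ticks)

  for (t in 0:horizon) {
    if (t > 0) {
      for (i in seq_len(M)) {
        n <- length(q_phase[[i]])
        if (n == 0L) next
        ph <- q_phase[[i]]; dn <- q_done[[i]]; rm_ <- q_rem[[i]]
        drop_head <- FALSE
        for (r in seq_len(n)) {
          if (ph[r] == 2L) {          # waiting: recheck the site ahead
            j <- dn[r] + 1L
            if (r == 1L || dn[r - 1L] >= j + D) {
              ph[r] <- 1L
              rm_[r] <- delays[[i]][j]
            }
            next
          }
          rm_[r] <- rm_[r] - 1L
          if (rm_[r] > 0L) next
          if (ph[r] == 0L) {          # initiation complete: enter codon 1
            j <- 1L
            if (j + D <= L[i] && r > 1L && dn[r - 1L] < j + D) {
              ph[r] <- 2L
            } else {
              ph[r] <- 1L
              rm_[r] <- delays[[i]][j]
            }
          } else {                    # codon dn[r] + 1 complete
            dn[r] <- dn[r] + 1L
            if (dn[r] == L[i]) {      # termination: protein, then diffusion
              proteins[i] <- proteins[i] + 1L
              .buf_push(prot_t, t); .buf_push(prot_i, i)
              pend_rel <- c(pend_rel, t + diff_d[i])
              drop_head <- TRUE      # no passing: only the leader terminates
            } else {
              j <- dn[r] + 1L
              if (j + D <= L[i] && r > 1L && dn[r - 1L] < j + D) {
                ph[r] <- 2L
              } else {
                ph[r] <- 1L
                rm_[r] <- delays[[i]][j]
              }
            }
          }
        }
        if (drop_head) {
          ph <- ph[-1L]; dn <- dn[-1L]; rm_ <- rm_[-1L]
        }
        q_phase[[i]] <- ph; q_done[[i]] <- dn; q_rem[[i]] <- rm_
        if (audit_gaps && length(ph) >= 2L) {
          pos <- ifelse(ph == 1L, dn + 1L, ifelse(ph == 2L, dn, NA_integer_))
          pos <- pos[!is.na(pos)]
          if (length(pos) >= 2L) {
            g <- min(pos[-length(pos)] - pos[-1L])
            if (g < min_gap) min_gap <- g
          }
        }
      }
      if (length(pend_rel)) {
        hit <- pend_rel <= t
        if (any(hit)) {
          free <- free + sum(hit)
          pend_rel <- pend_rel[!hit]
        }
      }
    }
    act <- lengths(q_phase)
    requesting <- which(act == 0L |
      vapply(seq_len(M), function(i) {
        n <- length(q_done[[i]])
        n > 0L && q_done[[i]][n] >= gate_codon[i]
      }, TRUE))
    tr_free[t + 1L] <- free
    tr_req[t + 1L] <- length(requesting)
    tr_act[t + 1L] <- sum(act)
    tr_dif[t + 1L] <- length(pend_rel)   # tracked independently of free/act
    it_max[t + 1L] <- max(act, 0L)
    if (t < horizon) {
      g <- integer(0)
      if (cycle_mode) {
        g <- arbiter_select(arb, requesting, free)   # one draw every cycle
      } else if (free > 0L && length(requesting)) {
        g <- arbiter_select(arb, requesting, free)
      }
      if (length(g)) {
        for (j in g) {
          q_phase[[j]] <- c(q_phase[[j]], 0L)
          q_done[[j]] <- c(q_done[[j]], 0L)
          q_rem[[j]] <- c(q_rem[[j]], init_d[j])
          grants[j] <- grants[j] + 1L
          if (length(q_phase[[j]]) > max_active[j])
            max_active[j] <- length(q_phase[[j]])
        }
        free <- free - length(g)
        .buf_push(gseq, g)
        .buf_push(gsize, length(g))
      }
    }
  }

  pt <- .buf_get(prot_t); pi <- .buf_get(prot_i)
  protein_times <- split(pt, factor(pi, levels = seq_len(M)))
  names(protein_times) <- ids
  structure(list(
    engine = "fixed_step", policy = arb$policy, seed = seed,
    horizon = horizon, delta_t = cell$delta_t, R = R, D = D, ids = ids,
    proteins = stats::setNames(proteins, ids),
    protein_times = protein_times,
    grants = stats::setNames(grants, ids),
    grant_seq = .buf_get(gseq),
    grant_sizes = .buf_get(gsize),
    max_active = stats::setNames(max_active, ids),
    trajectory = data.frame(
      time = 0:horizon, free = tr_free, free_mrnas = tr_req,
      active = tr_act, diffusing = tr_dif
    ),
    pool = data.frame(time = 0:horizon, free = tr_free),
    iter_time = 0:horizon, iter_max_active = it_max,
    iterations = ticks,
    min_gap = min_gap,
    final_free = free
  ), class = "sim_result")
}
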