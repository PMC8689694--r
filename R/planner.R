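#' Maximal simultaneously active ribosomes on one mRNA
#'
#' Upper bound `floor(L/D) + 1` for an mRNA of `L` codons and footprint `D`.
#'
#' @param L mRNA length in codons (>= 1).
#' @param D footprint in codons (>= 1).
#' @return integer bound (vectorized over `L`).
#' @export
max_active_ribosomes <- function(L, D) {
  stopifnot(all(L >= 1), D >= 1)
  as.integer(L %/% D + 1L)
}

#' Hardware speed factor and parallel-model runtime
#'
#' One hardware clock cycle retires one tick of `delta_t` seconds of real
#' cell time, so the decrement phase runs `delta_t * f` times faster than
#' the cell and a simulation of `T_sim` seconds takes `(T_sim/delta_t) / f`
#' seconds of wall time — independent of the numbers of ribosomes and mRNAs.
#'
#' @param T_sim simulated real-cell time in seconds.
#' @param delta_t tick length in seconds.
#' @param f clock frequency in Hz.
#' @return list with `speed_factor`, `cycles`, `runtime_seconds`.
#' @export
speed_and_runtime <- function(T_sim, delta_t, f) {
  stopifnot(T_sim > 0, delta_t > 0, f > 0)
  cycles <- T_sim / delta_t
  list(speed_factor = delta_t * f, cycles = cycles,
       runtime_seconds = cycles / f)
}

#' Distribute hardware ribosome slots among mRNAs
#'
#' Three allocation schemes for `HR` available hardware ribosome slots:
#' \describe{
#'   \item{max}{every mRNA gets its worst-case bound `floor(L_i/D) + 1`
#'     (ignores `HR`; never saturates).}
#'   \item{truncated}{uniform: twice the average cell-ribosome load per
#'     mRNA, `2 * ceiling(R/M)`, capped by the max bound.}
#'   \item{weighted}{proportional to a weight
#'     `w_i = log(1 + L_i * mean_delay_i / (init_i + D * mean_delay_i))`
#'     encoding the three drivers of occupancy — length, codon translation
#'     time, and entry time (initiation plus footprint clearance) — with
#'     logarithmic smoothing; `size_i = max(1, floor(HR * w_i / sum(w)))`,
#'     capped by the max bound. A custom `weight_fn(cell)` returning
#'     positive per-instance weights may replace it.}
#' }
#'
#' @param cell a [cell()] object.
#' @param HR total hardware slots (required and `>= M` for truncated /
#'   weighted).
#' @param method `"max"`, `"truncated"`, or `"weighted"`.
#' @param weight_fn optional replacement weight function (weighted only).
#' @return named integer vector of per-instance buffer sizes.
#' @export
allocate_buffers <- function(cell, HR = NULL,
                             method = c("max", "truncated", "weighted"),
                             weight_fn = NULL) {
  method <- match.arg(method)
  M <- length(cell$instances)
  ids <- vapply(cell$instances, `[[`, "", "id")
  L <- vapply(cell$instances, function(i) length(i$codons), 0L)
  bound <- max_active_ribosomes(L, cell$D)
  if (method == "max") return(stats::setNames(bound, ids))
  if (is.null(HR) || HR < M) {
    stop("truncated/weighted allocation needs HR >= M hardware slots")
  }
  if (method == "truncated") {
    size <- pmin(2L * as.integer(ceiling(cell$R / M)), bound)
    size <- pmax(size, 1L)
    return(stats::setNames(size, ids))
  }
  w <- if (!is.null(weight_fn)) weight_fn(cell) else {
    vapply(cell$instances, function(i) {
      md <- mean(i$delays)
      log(1 + length(i$codons) * md / (i$init_delay + cell$D * md))
    }, 0)
  }
  stopifnot(length(w) == M, all(w > 0))
  size <- pmax(1L, as.integer(floor(HR * w / sum(w))))
  size <- pmin(size, bound)
  # raising floors to 1 can overshoot HR when it is barely >= M: trim the
  # largest buffers back until the total fits
  while (sum(size) > HR) {
    k <- which.max(size)
    if (size[k] <= 1L) stop("cannot fit ", M, " mRNAs into ", HR, " slots")
    size[k] <- size[k] - 1L
  }
  stats::setNames(size, ids)
}

#' Saturation report for a buffer allocation
#'
#' Per-mRNA utilization is the maximum simultaneously active ribosomes
#' observed in a run divided by the allocated buffer size; an mRNA is
#' saturated when utilization reaches 1 (it would have missed grants in
#' hardware).
#'
#' @param result a `sim_result` with max-active tracking.
#' @param buffers named per-instance buffer sizes ([allocate_buffers()]).
#' @param breaks histogram bin edges on utilization.
#' @return list with `utilization` (named), `n_saturated`, `histogram`
#'   (data.frame `bin`, `count`).
#' @export
saturation_report <- function(result, buffers,
                              breaks = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(result, "sim_result"),
            setequal(names(buffers), result$ids))
  u <- result$max_active / buffers[result$ids]
  bins <- cut(pmin(u, 1), breaks = breaks, include.lowest = TRUE)
  list(
    utilization = u,
    n_saturated = sum(u >= 1),
    histogram = data.frame(
      bin = levels(bins),
      count = as.integer(table(bins))
    )
  )
}

#' ROM bit accounting for the codon-delay store
#'
#' A single ROM maps codon position to delay and costs
#' `NDbits * 2^ceil(log2 L)` bits per mRNA (block memories come in
#' power-of-two depths). The double-ROM scheme stores the 6-bit codon code
#' per position (`6 * 2^ceil(log2 L)` bits) plus one shared 64-entry
#' code-to-delay table (`64 * NDbits` bits, implementable as `NDbits`
#' 6-input lookup units and accounted separately). The improvement ratio on
#' the per-mRNA ROM component is `NDbits / 6`.
#'
#' @param L mRNA length in codons.
#' @param NDbits delay bit width (15 for the E. coli parameterisation).
#' @param scheme `"single"` or `"double"`.
#' @return list with `rom_bits`, `table_bits` (0 for single), `ratio`
#'   (single ROM bits / double ROM bits).
#' @export
rom_bits <- function(L, NDbits, scheme = c("single", "double")) {
  scheme <- match.arg(scheme)
  stopifnot(L >= 1, NDbits >= 1)
  depth <- 2^ceiling(log2(L))
  single <- NDbits * depth
  double <- 6 * depth
  if (scheme == "single") {
    list(rom_bits = single, table_bits = 0, ratio = single / double)
  } else {
    list(rom_bits = double, table_bits = 64 * NDbits, ratio = single / double)
  }
}

#' Mean clock cycles per iteration of the iterative hardware model
#'
#' In the iterative design one state machine serves all of an mRNA's
#' ribosomes sequentially, so each global iteration takes as long as the
#' busiest mRNA: `max_i(active ribosomes on i) + overhead` cycles. Returns
#' the time-average over the run's iterations.
#'
#' @param result a `sim_result` (uses its per-iteration max-active record).
#' @param overhead fixed cycles per iteration (state-machine bookkeeping).
#' @return list with `mean_cycles` and `per_iteration` (numeric vector).
#' @export
iterative_iteration_cycles <- function(result, overhead = 2) {
  stopifnot(inherits(result, "sim_result"), overhead >= 0)
  per <- result$iter_max_active + overhead
  list(mean_cycles = mean(per), per_iteration = per)
}
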