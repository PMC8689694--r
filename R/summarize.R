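#' Summaries of a simulation run
#'
#' Per-mRNA translation rates in proteins per second of real cell time
#' (`proteins / (horizon * delta_t)`), the simultaneous-grant histogram
#' normalized to fractions, the free-mRNA trajectory, and a per-mRNA
#' saturation flag (maximum simultaneously active ribosomes reached the
#' theoretical bound `floor(L/D) + 1`).
#'
#' @param result a `sim_result` from [run_event_driven()] or
#'   [run_fixed_step_oracle()].
#' @param cell the simulated cell (needed for the per-mRNA length bound; if
#'   omitted, saturation flags are `NA`).
#' @return list with `rates` (named, proteins/s), `grant_histogram`
#'   (data.frame `grants_per_event`, `fraction`), `free_mrnas` (data.frame
#'   `time`, `count`), `saturated` (named logical), `total_proteins`.
#' @export
summarize_result <- function(result, cell = NULL) {
  stopifnot(inherits(result, "sim_result"))
  span <- result$horizon * result$delta_t
  rates <- result$proteins / span
  hist <- NULL
  if (length(result$grant_sizes)) {
    tab <- table(result$grant_sizes)
    hist <- data.frame(
      grants_per_event = as.integer(names(tab)),
      fraction = as.numeric(tab) / length(result$grant_sizes)
    )
  } else {
    hist <- data.frame(grants_per_event = integer(0), fraction = numeric(0))
  }
  saturated <- rep(NA, length(result$ids))
  names(saturated) <- result$ids
  if (!is.null(cell)) {
    bound <- vapply(cell$instances,
                    function(i) length(i$codons) %/% cell$D + 1L, 0L)
    saturated <- stats::setNames(result$max_active >= bound, result$ids)
  }
  list(
    rates = rates,
    grant_histogram = hist,
    free_mrnas = data.frame(time = result$trajectory$time,
                            count = result$trajectory$free_mrnas),
    saturated = saturated,
    total_proteins = sum(result$proteins)
  )
}

#' Time-weighted mean of a step-function trajectory
#'
#' The free-pool and free-mRNA trajectories are right-continuous step
#' functions sampled at event times; the mean over `[from, to]` weights each
#' value by the time it persisted.
#'
#' @param time,value step-function knots (time ascending).
#' @param from,to integration window.
#' @return the time-average.
#' @export
trajectory_mean <- function(time, value, from, to) {
  stopifnot(to > from, length(time) == length(value))
  keep <- time <= to
  time <- time[keep]; value <- value[keep]
  if (!length(time)) return(NA_real_)
  # value holding at `from`: last knot at or before it (or first knot)
  start_idx <- max(1L, findInterval(from, time))
  t2 <- pmax(time, from)
  knots <- unique(c(from, t2[t2 >= from & t2 <= to], to))
  vals <- value[pmax(1L, findInterval(knots[-length(knots)], time))]
  sum(vals * diff(knots)) / (to - from)
}
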