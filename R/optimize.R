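#' Configuration for silent-mutation traffic optimization
#'
#' The optimizers introduce synonymous (silent) codon substitutions inside a
#' mutable region of each mRNA to enlarge the free ribosomal pool while
#' keeping every mRNA's protein production rate within a relative band
#' around its pre-optimization baseline.
#'
#' @param region 1-based inclusive codon positions open to mutation
#'   (default 11-50, sparing the initiation-proximal head of the ORF).
#' @param threshold allowed relative rate variation (e.g. 0.01 or 0.05);
#'   `|final - baseline| <= threshold * baseline` per mRNA.
#' @param horizon simulation horizon in ticks for objective evaluations.
#' @param burn_in fraction of the horizon discarded before averaging the
#'   free-pool trajectory (default 0.2).
#' @param policy,seed simulation policy and seed; all candidate evaluations
#'   share them (common random numbers), so greedy comparisons are
#'   meaningful under stochastic policies.
#' @param delay_table named 64-entry codon-to-delay table (ticks) used to
#'   look up replacement delays; defaults to the table attached to a
#'   [generate_cell()] cell.
#' @return list of class `optimization_config`.
#' @export
optimization_config <- function(region = c(11L, 50L), threshold = 0.01,
                                horizon = 2000L, burn_in = 0.2,
                                policy = "round_robin", seed = 1L,
                                delay_table = NULL) {
  stopifnot(length(region) == 2, region[1] >= 1, region[1] <= region[2],
            threshold >= 0, threshold < 1, burn_in >= 0, burn_in < 1,
            horizon >= 1)
  structure(list(region = as.integer(region), threshold = threshold,
                 horizon = as.integer(horizon), burn_in = burn_in,
                 policy = policy, seed = seed, delay_table = delay_table),
            class = "optimization_config")
}

#' Free-pool objective and per-species translation rates
#'
#' Runs the event-driven simulator, discards the burn-in window, and returns
#' the time-average of the free-pool trajectory together with per-species
#' protein production rates over the retained window (proteins per second
#' of real cell time, summed over a species' copies).
#'
#' @param cell a [cell()] object.
#' @param horizon simulation horizon in ticks.
#' @param burn_in fraction of the horizon discarded (in `[0, 1)`).
#' @param policy,seed passed to [run_event_driven()].
#' @return list with `mean_free`, `rates` (named per species), `result`
#'   (the full `sim_result`).
#' @export
evaluate_objective <- function(cell, horizon, burn_in = 0.2,
                               policy = "round_robin", seed = 1L) {
  stopifnot(burn_in >= 0, burn_in < 1)
  from <- burn_in * horizon
  if (horizon - from < 1) stop("horizon too short for the burn-in window")
  res <- run_event_driven(cell, horizon, policy, seed)
  mean_free <- trajectory_mean(res$pool$time, res$pool$free, from, horizon)
  window_s <- (horizon - from) * cell$delta_t
  sp_of <- vapply(cell$instances, `[[`, "", "species")
  counts <- vapply(res$protein_times, function(tt) sum(tt > from), 0)
  rates <- tapply(counts, factor(sp_of, levels = names(cell$species)), sum) / window_s
  list(mean_free = mean_free,
       rates = stats::setNames(as.numeric(rates), names(cell$species)),
       result = res)
}

#' Candidate silent mutations for one mRNA
#'
#' For each position of the mutable region (in scan order), the synonymous
#' replacement with the smallest table delay, kept only when strictly
#' smaller than the current codon's delay (ties between equally fast
#' synonyms broken alphabetically). Stop codons and codons without a faster
#' synonym yield no candidate.
#'
#' @param mrna an [mrna_spec()].
#' @param config an [optimization_config()] carrying region and delay table.
#' @param code a `genetic_code`.
#' @param direction `"forward"` (5' to 3' scan) or `"backward"`.
#' @return data.frame with `position`, `from`, `to`, `from_delay`,
#'   `to_delay`, ordered in scan direction; zero rows when nothing qualifies.
#' @export
candidate_mutations <- function(mrna, config, code = standard_genetic_code(),
                                direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  tab <- config$delay_table
  if (is.null(tab)) stop("optimization_config needs a delay_table")
  L <- length(mrna$codons)
  pos <- seq(max(1L, config$region[1]), min(L, config$region[2]))
  if (config$region[1] > L) pos <- integer(0)
  if (direction == "backward") pos <- rev(pos)
  rows <- lapply(pos, function(p) {
    cur <- mrna$codons[p]
    if (cur %in% code$stops) return(NULL)
    syn <- setdiff(code$synonyms[[cur]], cur)
    if (!length(syn)) return(NULL)
    syn <- syn[order(tab[syn], syn)]   # fastest, then alphabetical
    best <- syn[1]
    if (tab[best] >= mrna$delays[p]) return(NULL)
    data.frame(position = p, from = cur, to = best,
               from_delay = as.integer(mrna$delays[p]),
               to_delay = as.integer(tab[best]))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(position = integer(0), from = character(0),
                      to = character(0), from_delay = integer(0),
                      to_delay = integer(0)))
  }
  do.call(rbind, rows)
}

#' Apply one synonymous substitution to a cell
#'
#' Replaces the codon (and its delay) at `position` of species
#' `species_id`, in the species and every expanded copy.
#'
#' @param cell a `ribocell`.
#' @param species_id species identifier.
#' @param position 1-based codon position.
#' @param to replacement codon.
#' @param to_delay replacement delay in ticks.
#' @return the modified cell.
#' @export
apply_mutation <- function(cell, species_id, position, to, to_delay) {
  sp <- cell$species[[species_id]]
  if (is.null(sp)) stop("unknown species: ", species_id)
  sp$codons[position] <- to
  sp$delays[position] <- as.integer(to_delay)
  cell$species[[species_id]] <- sp
  for (k in seq_along(cell$instances)) {
    if (cell$instances[[k]]$species == species_id) {
      cell$instances[[k]]$codons[position] <- to
      cell$instances[[k]]$delays[position] <- as.integer(to_delay)
    }
  }
  cell
}

.gene_minimization <- function(cell, config, direction) {
  code <- standard_genetic_code()
  if (is.null(config$delay_table)) {
    tab <- attr(cell, "delay_table")
    if (is.null(tab)) stop("no delay_table in config and none attached to the cell")
    config$delay_table <- tab
  }
  sp_ids <- names(cell$species)
  cands <- lapply(cell$species, candidate_mutations, config = config,
                  code = code, direction = direction)
  pointer <- stats::setNames(rep(1L, length(sp_ids)), sp_ids)

  base <- evaluate_objective(cell, config$horizon, config$burn_in,
                             config$policy, config$seed)
  baseline_free <- base$mean_free
  baseline_rates <- base$rates
  tol <- config$threshold * baseline_rates

  cur_cell <- cell
  cur_free <- baseline_free
  cur_eval <- base
  gain_per <- stats::setNames(rep(0, length(sp_ids)), sp_ids)
  plan <- data.frame(mrna_id = character(0), position = integer(0),
                     from = character(0), to = character(0))
  trace <- data.frame(step = integer(0), mrna_id = character(0),
                      position = integer(0), gain = numeric(0))
  step <- 0L
  repeat {
    best <- NULL
    for (s in sp_ids) {
      cn <- cands[[s]]
      while (pointer[s] <= nrow(cn)) {
        row <- cn[pointer[s], ]
        tent <- apply_mutation(cur_cell, s, row$position, row$to, row$to_delay)
        ev <- evaluate_objective(tent, config$horizon, config$burn_in,
                                 config$policy, config$seed)
        admissible <- all(abs(ev$rates - baseline_rates) <= tol + 1e-12)
        gain <- ev$mean_free - cur_free
        if (admissible && gain > 0) {
          if (is.null(best) || gain > best$gain) {
            best <- list(s = s, row = row, gain = gain, ev = ev)
          }
          break   # keep the pointer here; commit may or may not pick it
        }
        pointer[s] <- pointer[s] + 1L   # scanned once, discarded
      }
    }
    if (is.null(best)) break
    step <- step + 1L
    s <- best$s; row <- best$row
    cur_cell <- apply_mutation(cur_cell, s, row$position, row$to, row$to_delay)
    cur_free <- best$ev$mean_free
    cur_eval <- best$ev
    gain_per[s] <- gain_per[s] + best$gain
    pointer[s] <- pointer[s] + 1L
    plan <- rbind(plan, data.frame(mrna_id = s, position = row$position,
                                   from = row$from, to = row$to))
    trace <- rbind(trace, data.frame(step = step, mrna_id = s,
                                     position = row$position, gain = best$gain))
  }
  muts <- stats::setNames(tabulate(factor(plan$mrna_id, levels = sp_ids),
                                   nbins = length(sp_ids)), sp_ids)
  structure(list(
    direction = direction, plan = plan, trace = trace,
    baseline_free = baseline_free, final_free = cur_free,
    baseline_rates = baseline_rates, final_rates = cur_eval$rates,
    gain_per_mrna = gain_per, mutations_per_mrna = muts,
    effectiveness = ifelse(muts > 0, gain_per / pmax(muts, 1L), 0),
    cell = cur_cell, config = config
  ), class = "traffic_opt")
}

#' Forward gene minimization (FGM)
#'
#' Greedy enlargement of the free ribosomal pool by silent mutations.
#' Each mRNA scans its mutable region from the 5' end; in every iteration
#' each mRNA's next admissible mutation (synonymous, rate within the
#' threshold band of its baseline, strictly positive free-pool gain) is
#' evaluated and the best-gaining mRNA's mutation is committed. Stops when
#' no mRNA yields a strictly positive admissible gain. Mutations that fail
#' the test in their evaluation context are discarded and not revisited.
#'
#' @param cell a `ribocell`.
#' @param config an [optimization_config()].
#' @return object of class `traffic_opt`: the mutation plan, baseline and
#'   final mean free pool, per-mRNA rates, gains, mutation counts and
#'   effectiveness (gain per mutation), and the mutated cell.
#' @export
fgm <- function(cell, config = optimization_config()) {
  .gene_minimization(cell, config, "forward")
}

#' Backward gene minimization (BGM)
#'
#' Identical to [fgm()] but each mRNA scans its mutable region from the 3'
#' end backwards.
#'
#' @inheritParams fgm
#' @return object of class `traffic_opt`.
#' @export
bgm <- function(cell, config = optimization_config()) {
  .gene_minimization(cell, config, "backward")
}

#' Combine FGM and BGM per mRNA and rank by mutation effectiveness
#'
#' For each mRNA the method with the larger free-pool gain is selected
#' ("Max(FGM, BGM)"); effectiveness is the gain divided by the number of
#' mutations (0 when no mutations were made).
#'
#' @param fgm_res,bgm_res `traffic_opt` results from the same baseline cell.
#' @return list with `table` (data.frame `mrna_id`, `method`, `gain`,
#'   `mutations`, `effectiveness`, ranked by gain) and `total_gain`.
#' @export
combine_and_effectiveness <- function(fgm_res, bgm_res) {
  stopifnot(inherits(fgm_res, "traffic_opt"), inherits(bgm_res, "traffic_opt"))
  if (!isTRUE(all.equal(fgm_res$baseline_rates, bgm_res$baseline_rates)) ||
      !isTRUE(all.equal(fgm_res$baseline_free, bgm_res$baseline_free))) {
    stop("results come from different baselines")
  }
  ids <- names(fgm_res$gain_per_mrna)
  take_f <- fgm_res$gain_per_mrna >= bgm_res$gain_per_mrna
  gain <- ifelse(take_f, fgm_res$gain_per_mrna, bgm_res$gain_per_mrna)
  muts <- ifelse(take_f, fgm_res$mutations_per_mrna, bgm_res$mutations_per_mrna)
  eff <- ifelse(muts > 0, gain / pmax(muts, 1), 0)
  tab <- data.frame(
    mrna_id = ids,
    method = ifelse(take_f, "fgm", "bgm"),
    gain = as.numeric(gain),
    mutations = as.integer(muts),
    effectiveness = as.numeric(eff)
  )
  tab <- tab[order(-tab$gain, tab$mrna_id), ]
  rownames(tab) <- NULL
  list(table = tab, total_gain = sum(gain))
}

#' @export
print.traffic_opt <- function(x, ...) {
  cat("<traffic_opt>", x$direction, "scan:", nrow(x$plan), "mutations,",
      "free pool", round(x$baseline_free, 2), "->", round(x$final_free, 2), "\n")
  invisible(x)
}
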