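#' Configuration for the synthetic-cell generator
#'
#' The generator emulates the statistical structure the simulator assumes —
#' heterogeneous mRNA lengths, copy numbers, codon-specific delays,
#' initiation and diffusion delays — at a configurable scale. Defaults are
#' desk-scale but shaped like the bacterial regime: lengths lognormal with a
#' median around 300 codons, per-codon delays uniform integers in 5-30
#' ticks, initiation delays uniform in 50-500 ticks, a constant 10-tick
#' diffusion delay, and a 1 ms tick.
#'
#' @param n_species number of mRNA species.
#' @param copy_law `"uniform"` (integers in `copy_range`) or `"log_spread"`
#'   (rounded log-uniform over `copy_range`).
#' @param copy_range length-2 integer range of copies per species.
#' @param length_law `"lognormal"` (`length_median`, `length_sdlog`, clamped
#'   to `length_range`) or `"range"` (uniform integers over `length_range`).
#' @param length_median,length_sdlog,length_range length-law parameters
#'   (codons).
#' @param delay_range per-codon delay law: one delay per sense codon drawn
#'   once per run, uniform integers over this range (ticks). Stop codons
#'   take delay 1 (the terminating position's convention).
#' @param init_range per-mRNA initiation delay, uniform integers (ticks).
#' @param diffusion_delay constant diffusion delay (ticks).
#' @param R,D,delta_t cell-level parameters (see [cell()]).
#' @param seed master seed (the generator draws from the `"synthetic-cell"`
#'   sub-stream).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_species = 8,
                             copy_law = c("uniform", "log_spread"),
                             copy_range = c(1L, 3L),
                             length_law = c("lognormal", "range"),
                             length_median = 300, length_sdlog = 0.45,
                             length_range = c(30L, 2000L),
                             delay_range = c(5L, 30L),
                             init_range = c(50L, 500L),
                             diffusion_delay = 10L,
                             R = 64L, D = 10L, delta_t = 1e-3, seed = 1L) {
  cfg <- list(
    n_species = n_species, copy_law = match.arg(copy_law),
    copy_range = copy_range, length_law = match.arg(length_law),
    length_median = length_median, length_sdlog = length_sdlog,
    length_range = length_range, delay_range = delay_range,
    init_range = init_range, diffusion_delay = diffusion_delay,
    R = R, D = D, delta_t = delta_t, seed = seed
  )
  stopifnot(n_species >= 1, all(delay_range >= 1), all(init_range >= 1),
            diffusion_delay >= 1, all(length_range >= 1),
            all(copy_range >= 1), R >= 0, D >= 1, delta_t > 0)
  class(cfg) <- "generator_config"
  cfg
}

#' Bacterial-scale preset
#'
#' Thousands of mRNA copies competing for tens of thousands of ribosomes —
#' the regime of roughly 20,000-50,000 ribosomes and 4,100 mRNA molecules in
#' a bacterial cell. Heavy to simulate in full; intended for planner-scale
#' analyses and down-scaled simulation studies.
#'
#' @param seed master seed.
#' @return a [generator_config()].
#' @export
ecoli_scale_config <- function(seed = 1L) {
  generator_config(
    n_species = 512, copy_law = "log_spread", copy_range = c(1L, 40L),
    R = 25000L, D = 10L, delta_t = 1e-3, seed = seed
  )
}

#' Generate a synthetic cell
#'
#' Draws a 61-entry sense-codon delay table (one delay per codon species,
#' shared by all mRNAs, as a hardware code-to-delay table would be), then
#' per species a codon sequence, an initiation delay and a copy number, and
#' assembles a validated [cell()]. Deterministic in the config seed.
#'
#' @param config a [generator_config()].
#' @return a `ribocell`; the drawn delay table is attached as attribute
#'   `delay_table` (named integer vector over the 64 codons).
#' @export
generate_cell <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  rng <- rng_stream(derive_seed(config$seed, "synthetic-cell"))
  code <- standard_genetic_code()
  delay_table <- stats::setNames(integer(64), code$codons)
  dr <- config$delay_range
  delay_table[code$sense] <-
    dr[1] + rng$int(61, dr[2] - dr[1] + 1L) - 1L
  delay_table[code$stops] <- 1L   # termination-position convention

  draw_len <- function() {
    if (config$length_law == "lognormal") {
      z <- stats::qnorm(rng$unif(1))
      L <- round(exp(log(config$length_median) + config$length_sdlog * z))
      as.integer(min(max(L, config$length_range[1]), config$length_range[2]))
    } else {
      lr <- config$length_range
      lr[1] + rng$int(1, lr[2] - lr[1] + 1L) - 1L
    }
  }
  draw_copies <- function() {
    cr <- config$copy_range
    if (config$copy_law == "uniform") {
      cr[1] + rng$int(1, cr[2] - cr[1] + 1L) - 1L
    } else {
      u <- rng$unif(1)
      as.integer(round(exp(log(cr[1]) + u * (log(cr[2]) - log(cr[1])))))
    }
  }
  ir <- config$init_range
  species <- lapply(seq_len(config$n_species), function(i) {
    L <- draw_len()
    codons <- code$sense[rng$int(L, 61L)]
    mrna_spec(
      id = sprintf("syn%03d", i),
      codons = codons,
      delays = delay_table[codons],
      init_delay = ir[1] + rng$int(1, ir[2] - ir[1] + 1L) - 1L,
      diff_delay = config$diffusion_delay,
      copies = draw_copies()
    )
  })
  out <- cell(species, R = config$R, D = config$D, delta_t = config$delta_t)
  attr(out, "delay_table") <- delay_table
  out
}

#' Replicate species in proportion to abundance
#'
#' Largest-remainder apportionment of a total copy budget among species:
#' copy counts are proportional to abundance, floors are assigned first and
#' the remaining copies go to the largest fractional remainders, ties broken
#' by lexicographic species identifier. Zero-abundance species are excluded.
#'
#' @param species list of [mrna_spec()] objects.
#' @param abundance numeric vector (same length; >= 0, at least one > 0).
#' @param M_cap total copy budget (>= 1).
#' @return list of `mrna_spec` with `copies` set (species receiving 0 copies
#'   are dropped); copy counts sum to `M_cap`.
#' @export
replicate_by_abundance <- function(species, abundance, M_cap) {
  stopifnot(length(species) == length(abundance), all(abundance >= 0),
            any(abundance > 0))
  if (M_cap < 1) stop("copy budget must be >= 1 (a cell needs M >= 1)")
  keep <- abundance > 0
  species <- species[keep]
  abundance <- abundance[keep]
  ids <- vapply(species, `[[`, "", "id")
  quota <- M_cap * abundance / sum(abundance)
  base <- floor(quota)
  rem <- quota - base
  left <- M_cap - sum(base)
  if (left > 0) {
    ord <- order(-rem, ids)   # largest remainder, lexicographic tie-break
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  out <- Map(function(sp, k) { sp$copies <- as.integer(k); sp }, species, base)
  out[base > 0]
}
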