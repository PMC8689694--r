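#' Define one mRNA species
#'
#' An mRNA species carries a codon sequence of length `L`, a per-codon
#' translation delay (ticks), an initiation delay (time for a ribosome to
#' attach at the 5' end before elongation), a diffusion delay (time a
#' released ribosome spends before rejoining the free pool), and a copy
#' number. All delays are positive integers in ticks of the cell's time
#' quantum. Codon positions are 1-based in every user-facing interface.
#'
#' @param id character identifier.
#' @param codons character vector of codons (3-letter DNA/RNA strings).
#' @param delays integer vector of per-codon delays (ticks), length `L`.
#' @param init_delay initiation delay in ticks (>= 1).
#' @param diff_delay diffusion delay in ticks (>= 1).
#' @param copies copy number (>= 1).
#' @return object of class `mrna_spec`.
#' @export
mrna_spec <- function(id, codons, delays, init_delay, diff_delay, copies = 1L) {
  codons <- normalize_codon(codons)
  spec <- structure(list(
    id = as.character(id),
    codons = codons,
    delays = as.integer(delays),
    init_delay = as.integer(init_delay),
    diff_delay = as.integer(diff_delay),
    copies = as.integer(copies)
  ), class = "mrna_spec")
  msg <- .check_mrna(spec)
  if (length(msg)) stop("invalid mRNA '", id, "': ", paste(msg, collapse = "; "))
  spec
}

.check_mrna <- function(m) {
  msg <- character()
  L <- length(m$codons)
  if (L < 1) msg <- c(msg, "sequence is empty")
  if (length(m$delays) != L) msg <- c(msg, "delay list length != L")
  if (any(m$delays < 1)) msg <- c(msg, "codon delays must be >= 1 tick")
  if (m$init_delay < 1) msg <- c(msg, "initiation delay must be >= 1 tick")
  if (m$diff_delay < 1) msg <- c(msg, "diffusion delay must be >= 1 tick")
  if (m$copies < 1) msg <- c(msg, "copy number must be >= 1")
  msg
}

#' Assemble a whole-cell instance
#'
#' Expands each species to `copies` per-copy instances, all competing for a
#' shared pool of `R` ribosomes. `D` is the ribosome footprint: consecutive
#' ribosomes on one mRNA keep a gap of at least `D` codons. `delta_t` is the
#' length of one tick in seconds of real cell time (1 ms in the E. coli
#' setting).
#'
#' @param species list of [mrna_spec()] objects.
#' @param R ribosome pool size (>= 0; 0 is legal and produces no proteins).
#' @param D ribosome footprint in codons (>= 1).
#' @param delta_t tick length in seconds (> 0).
#' @return object of class `ribocell` with elements `species` (named list),
#'   `instances` (data-frame-free list of per-copy instances, each with
#'   `id`, `species`, and the species' sequence/delays), `R`, `D`, `delta_t`.
#' @export
cell <- function(species, R, D, delta_t = 1e-3) {
  if (inherits(species, "mrna_spec")) species <- list(species)
  stopifnot(length(species) >= 1, all(vapply(species, inherits, TRUE, "mrna_spec")))
  ids <- vapply(species, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate species identifiers")
  names(species) <- ids
  instances <- list()
  for (sp in species) {
    for (k in seq_len(sp$copies)) {
      inst <- sp
      inst$id <- if (sp$copies == 1) sp$id else paste0(sp$id, "#", k)
      inst$species <- sp$id
      instances[[length(instances) + 1]] <- inst
    }
  }
  obj <- structure(list(
    species = species, instances = instances,
    R = as.integer(R), D = as.integer(D), delta_t = as.numeric(delta_t)
  ), class = "ribocell")
  v <- validate_cell(obj)
  if (!v$valid) stop("invalid cell: ", paste(v$errors, collapse = "; "))
  obj
}

#' Validate a cell and report per-mRNA ribosome bounds
#'
#' Confirms all type invariants and reports, for each mRNA instance, the
#' theoretical bound `floor(L/D) + 1` on simultaneously bound ribosomes.
#'
#' @param x a `ribocell` (or a list with the same fields, pre-construction).
#' @return list with `valid` (logical), `errors` (character, one entry per
#'   violated invariant, tagged with the mRNA id), `M`, `R`, and
#'   `max_bound` (named integer vector per instance).
#' @export
validate_cell <- function(x) {
  errors <- character()
  if (length(x$instances) < 1) errors <- c(errors, "cell has no mRNA instances (M >= 1 required)")
  if (is.na(x$R) || x$R < 0) errors <- c(errors, "R must be >= 0")
  if (is.na(x$D) || x$D < 1) errors <- c(errors, "D must be >= 1")
  if (!is.finite(x$delta_t) || x$delta_t <= 0) errors <- c(errors, "delta_t must be > 0")
  bound <- integer(0)
  for (inst in x$instances) {
    m <- .check_mrna(inst)
    if (length(m)) errors <- c(errors, paste0(inst$id, ": ", m))
    bound[inst$id] <- length(inst$codons) %/% max(1L, x$D) + 1L
  }
  list(valid = length(errors) == 0, errors = errors,
       M = length(x$instances), R = x$R, max_bound = bound)
}

#' @export
print.ribocell <- function(x, ...) {
  L <- vapply(x$instances, function(i) length(i$codons), 0L)
  cat("<ribocell> M =", length(x$instances), "mRNA instances (",
      length(x$species), "species ), R =", x$R, ", D =", x$D,
      ", delta_t =", x$delta_t, "s\n")
  cat("  lengths:", min(L), "-", max(L), "codons\n")
  invisible(x)
}

#' @export
print.mrna_spec <- function(x, ...) {
  cat("<mrna_spec>", x$id, ":", length(x$codons), "codons, init",
      x$init_delay, "t, diffusion", x$diff_delay, "t, copies", x$copies, "\n")
  invisible(x)
}
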