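#' Read coding sequences from FASTA
#'
#' Sequences must be whole coding regions: length a multiple of 3. RNA
#' alphabets are normalized to DNA.
#'
#' @param path FASTA file.
#' @return named list of codon character vectors (one per record).
#' @export
read_coding_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    if (nchar(s) %% 3 != 0) {
      stop("sequence '", names(seqs)[i], "' length ", nchar(s),
           " is not a multiple of 3")
    }
    normalize_codon(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)))
  })
  names(out) <- names(seqs)
  out
}

#' Write coding sequences to FASTA
#'
#' @param codon_list named list of codon vectors.
#' @param path output file.
#' @export
write_coding_fasta <- function(codon_list, path) {
  lines <- unlist(lapply(names(codon_list), function(id) {
    c(paste0(">", id), paste0(codon_list[[id]], collapse = ""))
  }))
  writeLines(lines, path)
}

#' Read a codon delay table (TSV)
#'
#' Species-level tables have columns `codon`, `delay_ticks` (64 rows);
#' per-mRNA positional overrides use columns `mrna_id`, `position`,
#' `delay_ticks`.
#'
#' @param path TSV file.
#' @return for a species table, a named integer vector over the 64 codons;
#'   for an override table, a data.frame.
#' @export
read_delay_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("codon", "delay_ticks") %in% names(df))) {
    cd <- normalize_codon(df$codon)
    if (length(cd) != 64 || anyDuplicated(cd)) {
      stop("species delay table must have one row per codon (64 rows)")
    }
    if (any(df$delay_ticks < 1)) stop("delays must be >= 1 tick")
    return(stats::setNames(as.integer(df$delay_ticks), cd))
  }
  if (all(c("mrna_id", "position", "delay_ticks") %in% names(df))) {
    if (any(df$delay_ticks < 1)) stop("delays must be >= 1 tick")
    return(df)
  }
  stop("unrecognized delay table columns: ", paste(names(df), collapse = ", "))
}

#' Write a codon delay table (TSV)
#'
#' @param delay_table named integer vector over codons.
#' @param path output file.
#' @export
write_delay_table <- function(delay_table, path) {
  utils::write.table(
    data.frame(codon = names(delay_table),
               delay_ticks = as.integer(delay_table)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a cell to FASTA + TSV + JSON
#'
#' Emits `<stem>.fasta` (species coding sequences), `<stem>_delays.tsv`
#' (the codon delay table, when attached), and `<stem>.json` (cell
#' configuration: `R`, `D`, `delta_t_seconds`, per-species `copies`,
#' `init_delay_ticks`, `diffusion_delay_ticks`, and explicit per-codon
#' delays when no shared table applies). [load_cell()] reads them back to
#' an identical cell.
#'
#' @param cell a `ribocell`.
#' @param stem output path stem.
#' @return invisibly, the written file paths.
#' @export
write_cell <- function(cell, stem) {
  fasta <- paste0(stem, ".fasta")
  cfgf <- paste0(stem, ".json")
  write_coding_fasta(lapply(cell$species, `[[`, "codons"), fasta)
  tab <- attr(cell, "delay_table")
  files <- c(fasta, cfgf)
  mr <- lapply(cell$species, function(sp) {
    entry <- list(id = sp$id, copies = sp$copies,
                  init_delay_ticks = sp$init_delay,
                  diffusion_delay_ticks = sp$diff_delay)
    if (is.null(tab) || !identical(unname(tab[sp$codons]), unname(sp$delays))) {
      entry$delays_ticks <- as.integer(sp$delays)
    }
    entry
  })
  cfg <- list(R = cell$R, D = cell$D, delta_t_seconds = cell$delta_t,
              fasta = basename(fasta), mrnas = unname(mr))
  if (!is.null(tab)) {
    tsv <- paste0(stem, "_delays.tsv")
    write_delay_table(tab, tsv)
    cfg$delay_table <- basename(tsv)
    files <- c(files, tsv)
  }
  jsonlite::write_json(cfg, cfgf, auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Load a cell written by [write_cell()]
#'
#' @param stem path stem used when writing.
#' @return a `ribocell`.
#' @export
load_cell <- function(stem) {
  read_cell_config(paste0(stem, ".json"))
}

#' Read a cell configuration (JSON or YAML) plus FASTA/TSV side files
#'
#' The config lists `R`, `D`, `delta_t_seconds`, a `fasta` path, optionally
#' a `delay_table` TSV path, and per-mRNA entries (`id`, `copies`,
#' `init_delay_ticks`, `diffusion_delay_ticks`, optional `delays_ticks`).
#' Paths are resolved relative to the config file.
#'
#' @param path config file (`.json`, `.yaml`, or `.yml`).
#' @return a `ribocell`.
#' @export
read_cell_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  dir <- dirname(path)
  codons <- read_coding_fasta(file.path(dir, cfg$fasta))
  tab <- if (!is.null(cfg$delay_table))
    read_delay_table(file.path(dir, cfg$delay_table)) else NULL
  species <- lapply(cfg$mrnas, function(m) {
    cd <- codons[[m$id]]
    if (is.null(cd)) stop("mRNA ", m$id, " not present in FASTA")
    delays <- if (!is.null(m$delays_ticks)) as.integer(unlist(m$delays_ticks))
      else if (!is.null(tab)) unname(tab[cd])
      else stop("no delays for mRNA ", m$id)
    mrna_spec(m$id, cd, delays, m$init_delay_ticks,
              m$diffusion_delay_ticks, m$copies)
  })
  out <- cell(species, R = cfg$R, D = cfg$D, delta_t = cfg$delta_t_seconds)
  if (!is.null(tab)) attr(out, "delay_table") <- tab
  out
}

#' Write simulation outputs as CSV/JSON
#'
#' Emits `<stem>_trajectory.csv` (`time_tick`, `time_seconds`,
#' `free_ribosomes`, `free_mrnas`), `<stem>_mrnas.csv` (`mrna_id`,
#' `proteins`, `grants`, `max_active`) and `<stem>_summary.json`.
#'
#' @param result a `sim_result`.
#' @param stem output path stem.
#' @return invisibly, the written file paths.
#' @export
write_sim_result <- function(result, stem) {
  trajf <- paste0(stem, "_trajectory.csv")
  mrnf <- paste0(stem, "_mrnas.csv")
  sumf <- paste0(stem, "_summary.json")
  tr <- result$trajectory
  utils::write.csv(
    data.frame(time_tick = tr$time, time_seconds = tr$time * result$delta_t,
               free_ribosomes = tr$free, free_mrnas = tr$free_mrnas),
    trajf, row.names = FALSE)
  utils::write.csv(
    data.frame(mrna_id = result$ids, proteins = as.integer(result$proteins),
               grants = as.integer(result$grants),
               max_active = as.integer(result$max_active)),
    mrnf, row.names = FALSE)
  jsonlite::write_json(list(
    engine = result$engine, policy = result$policy, seed = result$seed,
    horizon = result$horizon, delta_t = result$delta_t, R = result$R,
    D = result$D, total_proteins = sum(result$proteins),
    total_grants = sum(result$grants), iterations = result$iterations,
    final_free = result$final_free
  ), sumf, auto_unbox = TRUE, digits = NA)
  invisible(c(trajf, mrnf, sumf))
}
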