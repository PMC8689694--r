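# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# single-mRNA, single-ribosome cell with a 10-tick production cycle
closed_form_cell <- function() {
  m <- mrna_spec("m1", c("ATG", "AAA", "TAA"), c(1L, 1L, 1L),
                 init_delay = 2L, diff_delay = 5L)
  cell(list(m), R = 1, D = 1, delta_t = 1e-3)
}

# seeded random small cell in the regime M <= 16, R <= 64, L <= 60
random_small_cell <- function(seed) {
  set.seed(seed)
  n_sp <- sample(1:6, 1)
  sp <- lapply(seq_len(n_sp), function(i) {
    L <- sample(3:40, 1)
    mrna_spec(paste0("g", i),
              decode_codon(sample(0:63, L, replace = TRUE)),
              sample(1:8, L, replace = TRUE),
              init_delay = sample(1:12, 1),
              diff_delay = sample(1:10, 1),
              copies = sample(1:3, 1))
  })
  cell(sp, R = sample(0:40, 1), D = sample(1:5, 1), delta_t = 1e-3)
}

# two-mRNA cell with one artificially slow codon inside the mutable region;
# initiation-limited so the slow codon costs pool occupancy, not rate
optimizer_toy <- function(slow_fixable = TRUE) {
  code <- standard_genetic_code()
  tab <- stats::setNames(rep(5L, 64), code$codons)
  tab[c("TTA", "TTG", "CTT", "CTC", "CTA")] <- 25L  # slow leucines
  tab["CTG"] <- 5L                                  # the fast synonym
  tab[code$stops] <- 1L
  seq_a <- rep("ATG", 30)                           # Met has no synonyms
  if (slow_fixable) seq_a[15] <- "TTA"
  seq_b <- rep("ATG", 30)
  sa <- mrna_spec("gA", seq_a, tab[seq_a], init_delay = 60L, diff_delay = 5L)
  sb <- mrna_spec("gB", seq_b, tab[seq_b], init_delay = 60L, diff_delay = 5L)
  cl <- cell(list(sa, sb), R = 8, D = 3, delta_t = 1e-3)
  attr(cl, "delay_table") <- tab
  cl
}

toy_opt_config <- function(threshold = 0.05, horizon = 3000L) {
  optimization_config(region = c(11L, 20L), threshold = threshold,
                      horizon = horizon,
                      delay_table = attr(optimizer_toy(), "delay_table"))
}

expect_conservation <- function(res, R) {
  tr <- res$trajectory
  expect_true(all(tr$free + tr$active + tr$diffusing == R))
}
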