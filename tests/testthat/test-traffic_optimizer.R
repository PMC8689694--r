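test_that("the objective matches run summaries and respects burn-in", {
  cl <- optimizer_toy()
  # burn_in = 0: rates coincide with summarize_result, aggregated by species
  ev <- evaluate_objective(cl, 2000, burn_in = 0)
  s <- summarize_result(ev$result, cl)
  expect_equal(ev$rates, s$rates[names(ev$rates)])
  expect_error(evaluate_objective(cl, 1, burn_in = 0.9), "burn-in")
  # the time-average lies inside the pool's observed range
  expect_gte(ev$mean_free, min(ev$result$pool$free))
  expect_lte(ev$mean_free, max(ev$result$pool$free))
})

test_that("shortening post-gate codon delays never shrinks the free pool", {
  # positions beyond the 5' gate codon (D + 1) shorten the ribosome's
  # holding time without raising the mRNA's request rate, so the mean free
  # pool cannot drop; positions at or before the gate also speed up request
  # generation and may legitimately drain the pool further
  base_delays <- c(4L, 6L, 8L, 6L, 4L, 8L, 6L, 4L, 6L, 8L)
  D <- 2L
  mk <- function(delays) {
    m <- mrna_spec("m", decode_codon(rep(1L, 10)), delays, 20L, 4L)
    cell(list(m), R = 4, D = D, delta_t = 1e-3)
  }
  ref <- evaluate_objective(mk(base_delays), 1500)$mean_free
  for (pos in (D + 2):length(base_delays)) {
    faster <- base_delays
    faster[pos] <- 1L
    expect_gte(evaluate_objective(mk(faster), 1500)$mean_free, ref - 1e-9)
  }
})

test_that("candidate mutations pick the fastest strictly-faster synonym", {
  cl <- optimizer_toy()
  cfg <- toy_opt_config()
  cand <- candidate_mutations(cl$species$gA, cfg)
  expect_identical(cand$position, 15L)
  expect_identical(cand$from, "TTA")
  expect_identical(cand$to, "CTG")
  # methionine-only mRNA: nothing to mutate
  expect_identical(nrow(candidate_mutations(cl$species$gB, cfg)), 0L)
  # backward direction only reverses candidate order
  tab <- attr(cl, "delay_table")
  seqs <- rep("ATG", 30); seqs[c(12, 18)] <- c("TTA", "CTC")
  sp <- mrna_spec("gC", seqs, tab[seqs], 60L, 5L)
  fw <- candidate_mutations(sp, cfg, direction = "forward")
  bw <- candidate_mutations(sp, cfg, direction = "backward")
  expect_identical(fw$position, c(12L, 18L))
  expect_identical(bw$position, c(18L, 12L))
  fw_sorted <- fw[order(fw$position), ]; rownames(fw_sorted) <- NULL
  bw_sorted <- bw[order(bw$position), ]; rownames(bw_sorted) <- NULL
  expect_identical(fw_sorted, bw_sorted)
})

test_that("FGM fixes the slow codon, grows the pool, and matches exhaustive search", {
  cl <- optimizer_toy()
  cfg <- toy_opt_config()
  res <- fgm(cl, cfg)
  expect_identical(res$plan$mrna_id, "gA")
  expect_identical(res$plan$position, 15L)
  expect_gt(res$final_free, res$baseline_free)
  # rate admissibility
  expect_true(all(abs(res$final_rates - res$baseline_rates) <=
                  cfg$threshold * res$baseline_rates + 1e-9))
  # exhaustive search over all admissible mutation subsets (here: the single
  # candidate in or out) agrees with the greedy gain
  base <- evaluate_objective(cl, cfg$horizon, cfg$burn_in)
  mut <- apply_mutation(cl, "gA", 15, "CTG", 5)
  best_exhaustive <- max(0, evaluate_objective(mut, cfg$horizon,
                                               cfg$burn_in)$mean_free -
                            base$mean_free)
  expect_equal(res$final_free - res$baseline_free, best_exhaustive)
  # idempotence: rerunning on the optimized cell yields no further gain
  res2 <- fgm(res$cell, cfg)
  expect_identical(nrow(res2$plan), 0L)
  expect_equal(res2$final_free, res2$baseline_free)
})

test_that("BGM shares the FGM contract with a reversed scan", {
  cl <- optimizer_toy()
  cfg <- toy_opt_config()
  f <- fgm(cl, cfg)
  b <- bgm(cl, cfg)
  # single admissible position: the two scans coincide
  expect_identical(f$plan, b$plan)
  expect_equal(f$final_free, b$final_free)
  expect_true(all(abs(b$final_rates - b$baseline_rates) <=
                  cfg$threshold * b$baseline_rates + 1e-9))
})

test_that("a zero threshold with rate-changing candidates yields an empty plan", {
  # elongation-limited cell: the pool is saturated, so removing the slow
  # codon raises the mRNA's own rate and violates a zero band
  code <- standard_genetic_code()
  tab <- stats::setNames(rep(5L, 64), code$codons)
  tab[c("TTA", "TTG", "CTT", "CTC", "CTA")] <- 25L
  tab["CTG"] <- 5L
  tab[code$stops] <- 1L
  seqs <- rep("ATG", 20); seqs[12] <- "TTA"
  sp <- mrna_spec("g", seqs, tab[seqs], init_delay = 1L, diff_delay = 1L)
  cl <- cell(list(sp), R = 50, D = 2, delta_t = 1e-3)
  attr(cl, "delay_table") <- tab
  cfg <- optimization_config(region = c(11, 20), threshold = 0,
                             horizon = 2000, delay_table = tab)
  res <- fgm(cl, cfg)
  expect_identical(nrow(res$plan), 0L)
  expect_equal(res$final_free, res$baseline_free)
})

test_that("objective is non-decreasing along committed greedy steps", {
  cl <- optimizer_toy()
  tab <- attr(cl, "delay_table")
  # add a second fixable codon so several steps commit
  seqs <- rep("ATG", 30); seqs[c(13, 17)] <- "TTA"
  cl$species$gA <- mrna_spec("gA", seqs, tab[seqs], 60L, 5L)
  cl <- cell(cl$species, R = 8, D = 3, delta_t = 1e-3)
  attr(cl, "delay_table") <- tab
  res <- fgm(cl, toy_opt_config())
  expect_gte(nrow(res$plan), 1L)
  expect_true(all(res$trace$gain > 0))
})

test_that("combining FGM and BGM takes the per-mRNA maximum", {
  cl <- optimizer_toy()
  cfg <- toy_opt_config()
  f <- fgm(cl, cfg)
  b <- bgm(cl, cfg)
  comb <- combine_and_effectiveness(f, b)
  per <- stats::setNames(comb$table$gain, comb$table$mrna_id)
  for (id in names(f$gain_per_mrna)) {
    expect_gte(per[[id]], f$gain_per_mrna[[id]])
    expect_gte(per[[id]], b$gain_per_mrna[[id]])
  }
  # an mRNA without mutations has effectiveness 0
  no_mut <- comb$table[comb$table$mutations == 0, ]
  expect_true(all(no_mut$effectiveness == 0))
  # mismatched baselines are rejected
  other <- fgm(optimizer_toy(slow_fixable = FALSE), cfg)
  expect_error(combine_and_effectiveness(f, other), "baseline")
})

test_that("all planned mutations are synonymous", {
  cl <- optimizer_toy()
  code <- standard_genetic_code()
  res <- fgm(cl, toy_opt_config())
  for (k in seq_len(nrow(res$plan))) {
    expect_identical(code$aa[[res$plan$from[k]]], code$aa[[res$plan$to[k]]])
  }
})
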