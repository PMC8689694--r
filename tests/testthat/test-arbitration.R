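test_that("round-robin scans cyclically and advances past the last grant", {
  arb <- make_arbiter("round_robin", 4)
  arb$pointer <- 2L
  expect_identical(round_robin_select(c(1L, 2L, 3L), 1L, arb), 2L)
  expect_identical(arb$pointer, 3L)
  expect_identical(round_robin_select(integer(0), 5L, arb), integer(0))
  expect_identical(arb$pointer, 3L)
  arb8 <- make_arbiter("round_robin", 8)
  expect_identical(arbiter_select(arb8, 1:8, 8L), 1:8)
  # determinism: same inputs, same grants
  a1 <- make_arbiter("round_robin", 8); a2 <- make_arbiter("round_robin", 8)
  for (k in 1:10) {
    req <- sort(sample(1:8, 4))
    expect_identical(arbiter_select(a1, req, 2L), arbiter_select(a2, req, 2L))
  }
})

test_that("grants never exceed free ribosomes and stay within requests", {
  for (pol in c("round_robin", "uniform")) {
    arb <- make_arbiter(pol, 16, seed = 5)
    set.seed(99)
    for (k in 1:50) {
      req <- sample(1:16, sample(0:16, 1))
      free <- sample(0:8, 1)
      g <- arbiter_select(arb, req, free)
      expect_lte(length(g), free)
      expect_lte(length(g), length(req))
      expect_true(all(g %in% req))
      expect_identical(anyDuplicated(g), 0L)
    }
  }
})

test_that("event-mode uniform grants are equiprobable among requesters", {
  arb <- make_arbiter("uniform", 8, seed = 21)
  n <- 6000
  picks <- integer(n)
  for (k in seq_len(n)) picks[k] <- uniform_select(c(2L, 5L, 7L), 1L, arb, "event")
  counts <- table(factor(picks, levels = c(2, 5, 7)))
  chi <- stats::chisq.test(as.vector(counts))
  expect_gt(chi$p.value, 0.001)
})

test_that("cycle-mode uniform draws regardless of mRNA state", {
  arb <- make_arbiter("uniform", 8, seed = 3, mode = "cycle")
  # all requesting: every cycle hits
  hits <- vapply(1:200, function(i) length(arbiter_select(arb, 1:8, 1L)), 0L)
  expect_true(all(hits == 1))
  # one requester among M: per-cycle hit probability 1/M
  arb2 <- make_arbiter("uniform", 16, seed = 4, mode = "cycle")
  n <- 8000
  hits2 <- vapply(seq_len(n), function(i)
    length(arbiter_select(arb2, 7L, 1L)), 0L)
  p_hat <- mean(hits2)
  se <- sqrt((1 / 16) * (15 / 16) / n)
  expect_lt(abs(p_hat - 1 / 16), 5 * se)
})

test_that("bernoulli_window matches exact binomial tails and is monotone", {
  expect_identical(bernoulli_window(1, 0.5), 2L)
  expect_identical(bernoulli_window(1, 1e-9), 2L)
  # m = 2, p_error = 0.5: W = 3 gives P(<2 successes) = 0.5 (not <), W = 4
  # gives 0.3125
  expect_identical(bernoulli_window(2, 0.5), 4L)
  expect_equal(stats::pbinom(1, 3, 0.5), 0.5)
  expect_equal(stats::pbinom(1, 4, 0.5), 0.3125)
  # minimality against the exact tail, over a grid
  for (m in c(2, 8, 32)) {
    for (pe in c(0.2, 0.05, 1e-3)) {
      W <- bernoulli_window(m, pe)
      expect_lt(stats::pbinom(1, W, 1 / m), pe)
      expect_gte(stats::pbinom(1, W - 1, 1 / m), pe)
    }
  }
  # monotone: non-increasing in p_error, non-decreasing in m
  ws_pe <- vapply(c(0.5, 0.1, 0.01, 1e-4), function(pe)
    bernoulli_window(16, pe), 0L)
  expect_false(is.unsorted(ws_pe))
  ws_m <- vapply(c(1, 2, 8, 64, 512), function(m)
    bernoulli_window(m, 0.01), 0L)
  expect_false(is.unsorted(ws_m))
})

test_that("bernoulli_window agrees with a Monte-Carlo estimate", {
  set.seed(11)
  m <- 8; pe <- 0.05
  W <- bernoulli_window(m, pe)
  sims <- matrix(stats::rbinom(2e4 * W, 1, 1 / m), ncol = W)
  p_hat <- mean(rowSums(sims) < 2)
  expect_lt(p_hat, pe + 3 * sqrt(pe * (1 - pe) / 2e4))
})

test_that("release counters are sized from the revisit window", {
  rc <- release_counter_bits(W = 700, D = 35, d_minimal = 20)
  expect_equal(rc$max_releases, 2)
  expect_identical(rc$bits, 2L)
  rc2 <- release_counter_bits(W = 100, D = 35, d_minimal = 20)
  expect_equal(rc2$max_releases, 1)
  expect_identical(rc2$bits, 1L)
  # doubling the window never decreases the bit count
  for (W in c(50, 100, 400, 1600)) {
    expect_gte(release_counter_bits(2 * W, 10, 5)$bits,
               release_counter_bits(W, 10, 5)$bits)
  }
})

test_that("neighbor bias separates round-robin from uniform arbitration", {
  expect_equal(neighbor_bias(c(1L, 2L, 3L, 4L), 4), 1)
  expect_equal(neighbor_bias(c(4L, 1L), 4), 1)    # wrap-around successor
  expect_equal(neighbor_bias(c(1L, 3L), 4), 0)
  # uniform grants sit at the unbiased level 1/M
  set.seed(8)
  seqs <- sample.int(64, 2e4, replace = TRUE)
  nb <- neighbor_bias(seqs, 64)
  se <- sqrt((1 / 64) * (63 / 64) / (2e4 - 1))
  expect_lt(abs(nb - 1 / 64), 5 * se)
  # round-robin in the all-free regime is maximally biased
  rr <- arbiter_bench(make_arbiter("round_robin", 64), 2000)
  expect_gt(rr$neighbor_bias, 10 / 64)
  un <- arbiter_bench(make_arbiter("uniform", 64, seed = 2), 20000)
  expect_lt(un$neighbor_bias, 5 / 64)
  expect_gt(un$chisq$p_value, 0.001)
})

test_that("round-robin bias shrinks as the cell saturates with ribosomes", {
  cfg <- function(R) generator_config(n_species = 8, length_median = 30,
    length_range = c(10L, 50L), init_range = c(5L, 30L),
    delay_range = c(2L, 8L), diffusion_delay = 5L, R = R, D = 4,
    copy_range = c(1L, 1L), seed = 17)
  bias_at <- function(R) {
    res <- run_event_driven(generate_cell(cfg(R)), 1500, "round_robin")
    neighbor_bias(res$grant_seq, length(res$ids))
  }
  expect_gt(bias_at(4), bias_at(256))
})
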