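test_that("the active-ribosome bound is floor(L/D) + 1 and sims respect it", {
  expect_identical(max_active_ribosomes(30, 10), 4L)
  expect_identical(max_active_ribosomes(9, 10), 1L)
  expect_identical(max_active_ribosomes(c(10, 11), 10), c(2L, 2L))
  for (s in c(3, 9)) {
    cl <- random_small_cell(s)
    res <- run_fixed_step_oracle(cl, 400)
    bound <- vapply(cl$instances, function(i)
      max_active_ribosomes(length(i$codons), cl$D), 0L)
    expect_true(all(res$max_active <= bound))
  }
})

test_that("speed factors and runtimes follow the clock arithmetic", {
  sr <- speed_and_runtime(60, 1e-3, 100e6)
  expect_equal(sr$speed_factor, 1e5)   # 1 ms ticks at 100 MHz
  sr2 <- speed_and_runtime(1200, 1e-3, 200e6)
  expect_equal(sr2$cycles, 1.2e6)
  expect_equal(sr2$runtime_seconds, 6e-3)
  # the formulas carry no dependence on R or M by construction; the factor
  # scales linearly in both delta_t and f
  expect_equal(speed_and_runtime(1, 2e-3, 100e6)$speed_factor, 2e5)
})

test_that("buffer allocation obeys budgets, bounds, and symmetry", {
  mk_identical <- function(M, L, R) {
    sp <- lapply(seq_len(M), function(i)
      mrna_spec(paste0("g", i), decode_codon(rep(1L, L)), rep(5L, L), 20L, 5L))
    cell(sp, R = R, D = 2, delta_t = 1e-3)
  }
  cl <- mk_identical(16, 40, 64)
  # truncated: 2 * ceiling(R/M), capped by the per-mRNA bound
  tr <- allocate_buffers(cl, HR = 256, method = "truncated")
  expect_true(all(tr == 8L))           # 2 * (64/16)
  # weighted: identical mRNAs get identical sizes, total within HR
  w <- allocate_buffers(cl, HR = 128, method = "weighted")
  expect_equal(length(unique(w)), 1L)
  expect_lte(sum(w), 128)
  expect_true(all(w >= 1))
  bound <- max_active_ribosomes(40, 2)
  expect_true(all(w <= bound))
  # max: the worst-case bound, no budget needed
  mx <- allocate_buffers(cl, method = "max")
  expect_true(all(mx == bound))
  expect_error(allocate_buffers(cl, HR = 8, method = "weighted"), "HR >= M")
})

test_that("weighted allocation tracks occupancy drivers directionally", {
  # a longer / slower / faster-initiating mRNA should get at least as many
  # slots as a short fast one
  long_slow <- mrna_spec("long", decode_codon(rep(1L, 80)), rep(9L, 80), 5L, 5L)
  short_fast <- mrna_spec("short", decode_codon(rep(1L, 10)), rep(2L, 10), 200L, 5L)
  cl <- cell(list(long_slow, short_fast), R = 16, D = 2, delta_t = 1e-3)
  w <- allocate_buffers(cl, HR = 32, method = "weighted")
  expect_gt(w[["long"]], w[["short"]])
})

test_that("saturation reports flag exhausted buffers", {
  cl <- random_small_cell(5)
  res <- run_fixed_step_oracle(cl, 400)
  mx <- allocate_buffers(cl, method = "max")
  rep_max <- saturation_report(res, mx)
  expect_identical(rep_max$n_saturated, 0L)
  ones <- stats::setNames(rep(1L, length(res$ids)), res$ids)
  rep_one <- saturation_report(res, ones)
  expect_identical(rep_one$n_saturated, sum(res$max_active >= 1))
  expect_equal(sum(rep_one$histogram$count), length(res$ids))
})

test_that("weighted allocation saturates no more mRNAs than truncated", {
  cfg <- generator_config(n_species = 10, length_median = 40,
    length_range = c(10L, 120L), init_range = c(5L, 60L),
    delay_range = c(2L, 10L), diffusion_delay = 5L, R = 40, D = 4,
    copy_range = c(1L, 1L), seed = 23)
  cl <- generate_cell(cfg)
  res <- run_event_driven(cl, 2500)
  HR <- 2L * cl$R
  sat <- function(method) saturation_report(
    res, allocate_buffers(cl, HR = HR, method = method))$n_saturated
  expect_lte(sat("weighted"), sat("truncated"))
})

test_that("ROM accounting reproduces the single/double scheme arithmetic", {
  s <- rom_bits(300, 15, "single")
  expect_equal(s$rom_bits, 15 * 512)
  d <- rom_bits(300, 15, "double")
  expect_equal(d$rom_bits, 6 * 512)
  expect_equal(d$table_bits, 64 * 15)
  expect_equal(d$ratio, 2.5)
  expect_equal(rom_bits(300, 6, "double")$ratio, 1)   # no saving at 6 bits
  # the double scheme's ROM component never loses when NDbits > 6
  for (L in c(10, 100, 1000)) {
    for (nb in 7:16) {
      expect_lte(rom_bits(L, nb, "double")$rom_bits,
                 rom_bits(L, nb, "single")$rom_bits)
    }
  }
})

test_that("iteration cycles are driven by the busiest mRNA plus overhead", {
  fake <- structure(list(iter_max_active = c(0L, 0L, 0L)), class = "sim_result")
  expect_equal(iterative_iteration_cycles(fake, overhead = 2)$mean_cycles, 2)
  fake2 <- structure(list(iter_max_active = c(3L, 5L)), class = "sim_result")
  expect_equal(iterative_iteration_cycles(fake2, overhead = 2)$mean_cycles, 6)
  # non-decreasing in R on a fixed synthetic cell
  cfg <- function(R) generator_config(n_species = 5, length_median = 30,
    length_range = c(10L, 50L), init_range = c(5L, 30L),
    delay_range = c(2L, 8L), diffusion_delay = 5L, R = R, D = 4, seed = 29)
  cyc <- vapply(c(2, 8, 32, 128), function(R)
    iterative_iteration_cycles(run_event_driven(generate_cell(cfg(R)),
                                                1500))$mean_cycles, 0)
  expect_false(is.unsorted(cyc))
})
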