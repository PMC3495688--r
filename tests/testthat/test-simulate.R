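test_that("reference generation is deterministic and uniform", {
  expect_identical(generate_reference(10, seed = 1), generate_reference(10, seed = 1))
  expect_false(identical(generate_reference(10, seed = 1),
                         generate_reference(10, seed = 2)))
  g <- generate_reference(2e5, seed = 3)
  comp <- table(strsplit(g, "")[[1]]) / nchar(g)
  expect_true(all(abs(comp - 0.25) < 0.01))
  expect_error(generate_reference(0), "length")
})

test_that("polymorphism injection matches its rate and records sites", {
  ref <- generate_reference(1e5, seed = 4)
  none <- apply_polymorphisms(ref, 0)
  expect_identical(none$genome, ref)
  expect_equal(nrow(none$sites), 0)

  p <- apply_polymorphisms(ref, 0.001, seed = 5)
  expect_true(abs(nrow(p$sites) - 100) < 3 * sqrt(100))
  expect_true(all(p$sites$alt != p$sites$ref))
  expect_false(anyDuplicated(p$sites$position) > 0)
  # mutated genome differs from reference exactly at the recorded sites
  gr <- strsplit(ref, "")[[1]]
  gm <- strsplit(p$genome, "")[[1]]
  expect_equal(which(gr != gm), p$sites$position)
})

test_that("clean-read sampling conserves totals and shapes the count spectrum", {
  g <- generate_reference(1e4, seed = 6)
  tab <- sample_clean_reads(g, 20, 5000, seed = 7)
  expect_equal(tab$total_reads, 5000)
  expect_equal(tab$read_length, 20)

  # uniform starts, few reads: birthday regime, nearly all counts 1
  u <- sample_clean_reads(generate_reference(1e5, seed = 8), 30, 1000,
                          abundance = "uniform", seed = 9)
  expect_gt(mean(u$counts == 1), 0.95)

  # default skewed profile at study scale satisfies the adequacy check
  sim <- simulate_reads(target_rate = 0, seed = 10)
  expect_true(coverage_adequacy(sim$observed_reads)$adequate)
})

test_that("error injection bookkeeps truth exactly and hits the closed form", {
  g <- generate_reference(2e4, seed = 11)
  clean <- sample_clean_reads(g, 25, 4e4, seed = 12)
  L <- 25

  zero <- inject_errors(clean, rep(0, L), seed = 13)
  expect_identical(zero$observed$sequences, clean$sequences)
  expect_identical(zero$observed$counts, clean$counts)
  expect_equal(zero$true_per_read_rate, 0)

  rho <- 0.01
  inj <- inject_errors(clean, rep(rho, L), seed = 14)
  expect_equal(inj$observed$total_reads, clean$total_reads)
  expect_equal(inj$true_per_read_rate, inj$n_error_reads / clean$total_reads)
  p_err <- 1 - (1 - rho)^L
  mc_sd <- sqrt(p_err * (1 - p_err) / clean$total_reads)
  expect_lt(abs(inj$true_per_read_rate - p_err), 3 * mc_sd)

  expect_error(inject_errors(clean, rep(0.6, L)), "0.5")
  expect_error(inject_errors(clean, rep(0.01, L - 1)), "length")
})

test_that("the dependent model produces more multi-error reads at equal base rates", {
  g <- generate_reference(2e4, seed = 15)
  clean <- sample_clean_reads(g, 35, 5e4, seed = 16)
  rates <- scale_position_rates(default_error_profile(35), 0.2)
  ind <- inject_errors(clean, rates, model = "independent", seed = 17)
  dep <- inject_errors(clean, rates, model = "dependent", seed = 17)
  expect_gt(mean(dep$n_errors >= 2), mean(ind$n_errors >= 2))
  # the chance of at least one error is the same under both models
  # (independent Monte-Carlo draws; 3 SDs of the difference of two
  # binomial proportions at p = 0.2, n = 5e4)
  expect_lt(abs(dep$true_per_read_rate - ind$true_per_read_rate),
            3 * sqrt(2 * 0.2 * 0.8 / 5e4))
})

test_that("profile scaling solves the per-read rate inversion", {
  prof <- default_error_profile(35)
  scaled <- scale_position_rates(prof, 0.2)
  expect_equal(1 - prod(1 - scaled), 0.2, tolerance = 1e-6)

  # flat profile closed form: 1 - (1-target)^(1/L)
  flat <- scale_position_rates(rep(1, 35), 0.2)
  expect_equal(flat[1], 1 - 0.8^(1 / 35), tolerance = 1e-8)
  expect_equal(length(unique(round(flat, 12))), 1)

  # fixed point: target equal to the profile's implied rate returns c = 1
  implied <- 1 - prod(1 - scaled)
  again <- scale_position_rates(scaled, implied)
  expect_equal(again, scaled, tolerance = 1e-6)

  # monotone: higher target, higher rates everywhere
  hi <- scale_position_rates(prof, 0.4)
  expect_true(all(hi > scaled))

  expect_error(scale_position_rates(rep(1, 5), 0.999), "unreachable")
})

test_that("simulate_reads is fully deterministic under a seed", {
  a <- simulate_reads(genome_length = 5e3, n_reads = 1e4, target_rate = 0.1,
                      seed = 18)
  b <- simulate_reads(genome_length = 5e3, n_reads = 1e4, target_rate = 0.1,
                      seed = 18)
  expect_identical(a$reference, b$reference)
  expect_identical(a$observed_reads$sequences, b$observed_reads$sequences)
  expect_identical(a$observed_reads$counts, b$observed_reads$counts)
  expect_identical(a$true_per_read_rate, b$true_per_read_rate)

  c <- simulate_reads(genome_length = 5e3, n_reads = 1e4, target_rate = 0.1,
                      seed = 19)
  expect_false(identical(a$reference, c$reference))

  # observed and clean tables conserve the read total
  expect_equal(a$observed_reads$total_reads, a$clean_reads$total_reads)
})
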