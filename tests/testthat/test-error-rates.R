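test_that("select_top_reads is deterministic and breaks ties lexicographically", {
  tab <- as_read_count_table(c(AAA = 3, CCC = 2, GGG = 1))
  expect_equal(select_top_reads(tab, 1000), c("AAA", "CCC", "GGG"))

  counts <- setNames(10:1, replicate(10, paste(sample(BASES, 4, TRUE), collapse = "")))
  # ensure unique names
  names(counts) <- sprintf("%s", c("AAAA","AAAC","AAAG","AAAT","AACA",
                                   "AACC","AACG","AACT","AAGA","AAGC"))
  tab2 <- as_read_count_table(counts)
  expect_equal(select_top_reads(tab2, 5), names(counts)[1:5])

  # tie at the k-th count: lexicographic, independent of input order
  tied <- c(TTTA = 5, AAAC = 5, CCCA = 5, GGGA = 1)
  t1 <- select_top_reads(as_read_count_table(tied), 2)
  t2 <- select_top_reads(as_read_count_table(rev(tied)), 2)
  expect_equal(t1, c("AAAC", "CCCA"))
  expect_identical(t1, t2)
})

test_that("coverage adequacy applies the max and range thresholds", {
  seqs <- c("AAAA", "CCCC", "GGGG")
  ok <- as_read_count_table(setNames(c(600, 50, 10), seqs))
  a <- coverage_adequacy(ok, k = 3)
  expect_equal(a$max_count, 600)
  expect_equal(a$count_range, 590)
  expect_true(a$adequate)

  low <- as_read_count_table(setNames(c(50, 40, 30), seqs))
  expect_false(coverage_adequacy(low, k = 3)$adequate)

  empty <- as_read_count_table(setNames(numeric(), character()))
  e <- coverage_adequacy(empty)
  expect_false(e$adequate)
  expect_equal(e$max_count, 0)
})

test_that("error-free reads from a non-repetitive genome estimate ~0", {
  sim <- simulate_reads(genome_length = 2e4, n_reads = 5e4, target_rate = 0,
                        seed = 31)
  fit <- suppressWarnings(shadow_regression(sim$observed_reads,
                                            per_position = FALSE))
  expect_lt(fit$error_rate, 0.005)
})

test_that("estimates are scale-equivariant and permutation invariant", {
  sim <- simulate_reads(genome_length = 2e4, n_reads = 5e4, target_rate = 0.1,
                        seed = 32)
  tab <- sim$observed_reads
  fit1 <- shadow_regression(tab, per_position = FALSE)

  doubled <- as_read_count_table(setNames(tab$counts * 2, tab$sequences))
  fit2 <- shadow_regression(doubled, per_position = FALSE)
  expect_equal(fit2$error_rate, fit1$error_rate, tolerance = 1e-10)

  perm <- sample(length(tab$sequences))
  shuffled <- as_read_count_table(setNames(tab$counts[perm], tab$sequences[perm]))
  fit3 <- shadow_regression(shuffled, per_position = FALSE)
  expect_identical(fit3$error_rate, fit1$error_rate)
})

test_that("estimates increase monotonically with the injected error rate", {
  rates <- c(0.05, 0.15, 0.25, 0.35)
  ests <- vapply(rates, function(r) {
    sim <- simulate_reads(genome_length = 2e4, n_reads = 5e4, target_rate = r,
                          seed = 33)  # matched seed across rates
    shadow_regression(sim$observed_reads, per_position = FALSE)$error_rate
  }, 0)
  expect_true(all(diff(ests) > 0))
})

test_that("high injected rates are underestimated (shadow truncation at 2 edits)", {
  for (s in 1:3) {
    sim <- simulate_reads(genome_length = 2e4, n_reads = 5e4, target_rate = 0.45,
                          seed = 40 + s)
    fit <- shadow_regression(sim$observed_reads, per_position = FALSE)
    expect_lt(fit$error_rate, sim$true_per_read_rate)
  }
})

test_that("per-position estimates localize errors injected at one position", {
  # a flatter abundance profile keeps the (few) error-shadow sequences of the
  # most frequent reads below the top-k cutoff, so concentrating all errors at
  # a single position remains observable
  g <- generate_reference(2e4, seed = 50)
  clean <- sample_clean_reads(g, 35, 2e5, exponent = 0.5, seed = 50)
  rates <- rep(0, 35)
  rates[10] <- 0.06
  inj <- inject_errors(clean, rates, seed = 51)
  fit <- shadow_regression(inj$observed, top_k = 500, per_position = TRUE,
                           adequacy_warn = FALSE)
  pp <- fit$per_position$rate
  expect_equal(pp[10], 0.06, tolerance = 0.02 / 0.06)
  expect_true(all(pp[-10] < 0.01))
  # per-read rate matches the single-position injection probability
  expect_lt(abs(fit$error_rate - inj$true_per_read_rate), 0.02)
})

test_that("a flat injected profile yields a flat per-position estimate", {
  sim <- simulate_reads(genome_length = 2e4, n_reads = 1e5, target_rate = 0,
                        seed = 52)
  L <- sim$clean_reads$read_length
  inj <- inject_errors(sim$clean_reads, rep(0.004, L), seed = 53)
  fit <- shadow_regression(inj$observed, per_position = TRUE,
                           adequacy_warn = FALSE)
  pp <- fit$per_position$rate
  expect_true(all(abs(pp - 0.004) < 0.004))
  expect_lt(sd(pp), 0.002)
})

test_that("indel estimates mask read extremes and report zero on clean data", {
  sim <- simulate_reads(genome_length = 2e4, n_reads = 5e4, target_rate = 0,
                        seed = 54)
  fit <- suppressWarnings(shadow_regression(sim$observed_reads,
                                            error_type = "insertion",
                                            per_position = TRUE))
  L <- sim$clean_reads$read_length
  expect_true(all(is.na(fit$per_position$rate[c(1, 2, L - 1, L)])))
  mid <- fit$per_position$rate[3:(L - 2)]
  expect_true(all(mid[!is.na(mid)] < 0.01))
  expect_lt(fit$error_rate, 0.005)
})

test_that("error_type='all' sums the per-type estimates", {
  sim <- simulate_reads(genome_length = 2e4, n_reads = 5e4, target_rate = 0.1,
                        seed = 55)
  fit <- suppressWarnings(shadow_regression(sim$observed_reads,
                                            error_type = "all",
                                            per_position = FALSE))
  expect_named(fit$components, c("substitution", "insertion", "deletion"))
  expect_equal(fit$error_rate,
               sum(vapply(fit$components, `[[`, 0, "error_rate")))
})

test_that("repetitiveness test separates random from engineered repetitive genomes", {
  g <- generate_reference(1e5, seed = 7)
  rt <- repetitiveness_test(g, read_length = 36, n_reads = 2e5, seed = 8)
  expect_lt(rt$estimate, 0.005)
  expect_false(rt$repetitive)

  rep_g <- make_repetitive_genome(seed = 9)
  rt2 <- repetitiveness_test(rep_g, read_length = 36, n_reads = 2e5, seed = 10)
  expect_true(rt2$repetitive)
  expect_gt(rt2$estimate, 0.005)

  # an absurd threshold never flags
  rt3 <- repetitiveness_test(rep_g, read_length = 36, n_reads = 5e4,
                             seed = 10, threshold = 1.0)
  expect_false(rt3$repetitive)

  expect_error(repetitiveness_test("ACGT", read_length = 36), "longer than")
})

test_that("model object methods behave like a classed fit", {
  sim <- simulate_reads(genome_length = 2e4, n_reads = 5e4, target_rate = 0.1,
                        seed = 60)
  fit <- shadow_regression(sim$observed_reads, per_position = TRUE)
  expect_s3_class(fit, "shadow_regression")
  expect_named(coef(fit), c("intercept", "slope"))
  expect_equal(predict(fit, newdata = data.frame(n = c(0, 1))),
               c(fit$fit$intercept, fit$fit$intercept + fit$fit$slope))
  expect_length(residuals(fit), fit$top_k)
  expect_equal(fitted(fit) + residuals(fit), fit$points$s, tolerance = 1e-8)
  expect_output(print(fit), "per-read error rate")
  expect_output(print(summary(fit)), "per-position")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
  expect_silent(plot(fit, which = "positions"))
})
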