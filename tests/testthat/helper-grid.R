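# Shared replicate grid for the simulation-accuracy checks. Computed once per
# test run and cached: for each seed, one set of error-free reads is drawn and
# errors at every target rate under both models are injected into it (mirroring
# a design where one pool of error-free reads underlies all rates).
.grid_cache <- new.env(parent = emptyenv())

simulation_grid <- function(n_seeds = 20,
                            rates = c(0.05, 0.10, 0.15, 0.20, 0.25),
                            genome_length = 1e5, read_length = 35,
                            n_reads = 2e5, base_seed = 20120730) {
  key <- paste(n_seeds, paste(rates, collapse = "_"), genome_length,
               n_reads, base_seed, sep = "|")
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  profile <- default_error_profile(read_length)
  rows <- list()
  for (s in seq_len(n_seeds)) {
    clean <- with_seed_local(base_seed + s, {
      ref <- generate_reference(genome_length)
      sample_clean_reads(ref, read_length, n_reads)
    })
    for (model in c("independent", "dependent")) {
      for (r in rates) {
        pos_rates <- scale_position_rates(profile, r)
        inj <- inject_errors(clean, pos_rates, model = model,
                             seed = base_seed + 1000L * s + round(1000 * r) +
                               ifelse(model == "dependent", 500000L, 0L))
        fit <- shadow_regression(inj$observed, per_position = FALSE,
                                 adequacy_warn = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          seed = s, model = model, target_rate = r,
          truth = inj$true_per_read_rate, estimate = fit$error_rate)
      }
    }
  }
  res <- do.call(rbind, rows)
  .grid_cache[[key]] <- res
  res
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
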