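#' Generate a uniform-random reference sequence
#'
#' @param length sequence length in bases (>= 1).
#' @param seed optional RNG seed.
#' @return A single character string over A/C/G/T.
#' @export
generate_reference <- function(length, seed = NULL) {
  stopifnot(is.numeric(length), length >= 1)
  with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
}

#' Inject polymorphisms into a reference
#'
#' Creates a "sample genome" differing from the reference at independently
#' chosen sites: each position mutates with probability `rate` to a uniformly
#' chosen different base. Models genuine sample-reference differences (e.g.
#' ~1/1000 bp for human polymorphism) that mismatch counting misreads as
#' sequencing error.
#'
#' @param reference reference sequence string.
#' @param rate per-base polymorphism probability in `[0, 1)`.
#' @param seed optional RNG seed.
#' @return List with `genome` (mutated sequence) and `sites` (data frame of
#'   `position`, `ref`, `alt`).
#' @export
apply_polymorphisms <- function(reference, rate, seed = NULL) {
  stopifnot(is.character(reference), length(reference) == 1)
  stopifnot(rate >= 0, rate < 1)
  n <- nchar(reference)
  with_seed(seed, {
    sites <- which(runif(n) < rate)
    if (length(sites) == 0)
      return(list(genome = reference,
                  sites = data.frame(position = integer(), ref = character(),
                                     alt = character())))
    bases <- c("A", "C", "G", "T")
    refb <- substring(reference, sites, sites)
    altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1), "")
    g <- strsplit(reference, "", fixed = TRUE)[[1]]
    g[sites] <- altb
    list(genome = paste(g, collapse = ""),
         sites = data.frame(position = sites, ref = refb, alt = unname(altb),
                            row.names = NULL))
  })
}

#' Sample error-free reads from a genome
#'
#' Draws `n_reads` fixed-length forward-strand reads whose start positions
#' follow a skewed abundance profile, so that the resulting count spectrum has
#' the heavy head and long tail seen in real count data (a few reads very
#' frequent, most reads rare) — the structure shadow regression relies on.
#' The default profile assigns Zipf weights (rank^-exponent) to a random
#' permutation of start positions; `abundance = "uniform"` draws starts
#' uniformly.
#'
#' @param genome genome sequence string.
#' @param read_length read length (< genome length).
#' @param n_reads number of read copies to draw.
#' @param abundance `"zipf"` (default) or `"uniform"`.
#' @param exponent Zipf exponent; 1 reproduces a classic rank-frequency law
#'   and comfortably satisfies the coverage-adequacy check at the default
#'   simulation scale.
#' @param seed optional RNG seed.
#' @return A `read_count_table` of error-free reads (total = `n_reads`).
#' @export
sample_clean_reads <- function(genome, read_length, n_reads,
                               abundance = c("zipf", "uniform"),
                               exponent = 1, seed = NULL) {
  abundance <- match.arg(abundance)
  G <- nchar(genome)
  stopifnot(G > read_length, n_reads >= 1)
  npos <- G - read_length + 1
  with_seed(seed, {
    if (abundance == "zipf") {
      w <- (seq_len(npos))^(-exponent)
      w <- w[sample.int(npos)] # random position gets random rank
      starts <- sample.int(npos, size = n_reads, replace = TRUE, prob = w)
    } else {
      starts <- sample.int(npos, size = n_reads, replace = TRUE)
    }
    reads <- substring(genome, starts, starts + read_length - 1)
    table_from_reads(reads)
  })
}

#' Inject substitution errors into clean reads
#'
#' Implements the two simulation error models. Every read copy is mutated
#' base by base: under the independent model position i flips with its
#' pre-specified rate; under the dependent model the per-position rates
#' double for all positions downstream of the first realized error in the
#' read (error bursts). Substituted bases are uniform over the three
#' alternatives. The realized per-read error rate — the exact fraction of
#' read copies that received at least one error — is bookkept, not estimated.
#'
#' @param clean a `read_count_table` of error-free reads.
#' @param position_rates per-position substitution rates, length =
#'   read length, each in `[0, 0.5)` (so the dependent doubling stays below 1).
#' @param model `"independent"` or `"dependent"`.
#' @param seed optional RNG seed.
#' @return List with `observed` (a `read_count_table`, same total as `clean`),
#'   `true_per_read_rate`, `n_error_reads`, and `n_errors` (per-copy error
#'   counts).
#' @export
inject_errors <- function(clean, position_rates,
                          model = c("independent", "dependent"), seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(clean, "read_count_table"))
  L <- clean$read_length
  if (length(position_rates) != L)
    stop("position_rates must have length ", L, " (the read length)")
  if (any(position_rates < 0) || any(position_rates >= 0.5))
    stop("per-position rates must lie in [0, 0.5)")
  copies <- rep(clean$sequences, times = clean$counts)
  res <- with_seed(seed,
    cpp_inject_errors(copies, as.numeric(position_rates),
                      model == "dependent"))
  observed <- table_from_reads(res$reads, prefiltered = TRUE)
  n_err <- sum(res$n_errors > 0)
  list(observed = observed,
       true_per_read_rate = n_err / length(copies),
       n_error_reads = n_err,
       n_errors = res$n_errors)
}

#' Scale a per-position error profile to a target per-read rate
#'
#' Finds the constant c such that rates `c * base_profile` imply a per-read
#' error probability (the chance a read carries at least one error) equal to
#' `target_per_read_rate`. Under both error models the probability of a read
#' being error free is `prod(1 - c * p_i)` — the dependent model's doubling
#' only affects positions after the first error — so a single bisection serves
#' both.
#'
#' @param base_profile nonnegative per-position rate shape, length = read
#'   length.
#' @param target_per_read_rate desired per-read error probability in `(0, 1)`.
#' @param cap upper bound any scaled rate may reach (default 0.5, the validity
#'   limit of the dependent model).
#' @param tol bisection tolerance on the implied per-read rate.
#' @return Scaled rate vector.
#' @examples
#' # flat profile, L = 35, target 0.20: each rate = 1 - 0.8^(1/35)
#' r <- scale_position_rates(rep(1, 35), 0.2)
#' all.equal(r[1], 1 - 0.8^(1 / 35))
#' @export
scale_position_rates <- function(base_profile, target_per_read_rate,
                                 cap = 0.5, tol = 1e-6) {
  stopifnot(all(base_profile >= 0), any(base_profile > 0))
  stopifnot(target_per_read_rate > 0, target_per_read_rate < 1)
  implied <- function(cc) 1 - prod(1 - cc * base_profile)
  cmax <- (cap - 1e-12) / max(base_profile)
  if (implied(cmax) < target_per_read_rate)
    stop("target per-read rate ", target_per_read_rate,
         " is unreachable with per-position rates capped at ", cap)
  cc <- stats::uniroot(function(x) implied(x) - target_per_read_rate,
                       lower = 0, upper = cmax,
                       tol = .Machine$double.eps^0.75)$root
  stopifnot(abs(implied(cc) - target_per_read_rate) < tol)
  cc * base_profile
}

#' Default per-cycle error profile shape
#'
#' Sequencing error rates typically rise along the read (later cycles are
#' noisier). The default simulation profile increases linearly four-fold from
#' the first to the last cycle; it is a shape only — [scale_position_rates()]
#' sets its level.
#'
#' @param read_length read length.
#' @return Numeric vector of relative rates.
#' @export
default_error_profile <- function(read_length) {
  seq(1, 4, length.out = read_length)
}

#' Simulate a ground-truth sequencing dataset
#'
#' End-to-end generator for validating the estimators: draws a uniform-random
#' reference, optionally injects polymorphisms to form the sample genome,
#' samples error-free reads with a skewed abundance profile, scales the
#' per-position error profile to the target per-read rate, and injects
#' substitution errors under the chosen model. All ground truth is bookkept
#' exactly.
#'
#' The defaults (100 kb genome, 35 bp reads, 2e5 reads, Zipf abundance,
#' linearly increasing error profile) define the standard validation
#' conditions used throughout the package's tests.
#'
#' @param genome_length reference length in bases.
#' @param read_length read length in bases.
#' @param n_reads number of read copies.
#' @param target_rate target per-read error rate (probability a read carries
#'   at least one error); 0 disables error injection.
#' @param model `"independent"` or `"dependent"` error model.
#' @param polymorphism_rate per-base reference/sample difference rate.
#' @param base_profile per-position error profile shape; defaults to
#'   [default_error_profile()].
#' @param abundance_exponent Zipf exponent of the read-abundance profile.
#' @param seed optional RNG seed governing the whole dataset.
#' @return An object of class `shadow_sim`: list with `reference`,
#'   `sample_genome`, `polymorphism_sites`, `clean_reads`, `observed_reads`,
#'   `position_rates`, `true_per_read_rate`, `model`, `seed`.
#' @export
simulate_reads <- function(genome_length = 1e5, read_length = 35,
                           n_reads = 2e5, target_rate = 0.2,
                           model = c("independent", "dependent"),
                           polymorphism_rate = 0, base_profile = NULL,
                           abundance_exponent = 1, seed = NULL) {
  model <- match.arg(model)
  if (is.null(base_profile)) base_profile <- default_error_profile(read_length)
  with_seed(seed, {
    reference <- generate_reference(genome_length)
    poly <- apply_polymorphisms(reference, polymorphism_rate)
    clean <- sample_clean_reads(poly$genome, read_length, n_reads,
                                abundance = "zipf",
                                exponent = abundance_exponent)
    if (target_rate > 0) {
      rates <- scale_position_rates(base_profile, target_rate)
      inj <- inject_errors(clean, rates, model = model)
    } else {
      rates <- rep(0, read_length)
      inj <- list(observed = clean, true_per_read_rate = 0, n_error_reads = 0,
                  n_errors = integer(clean$total_reads))
    }
    structure(list(reference = reference, sample_genome = poly$genome,
                   polymorphism_sites = poly$sites, clean_reads = clean,
                   observed_reads = inj$observed, position_rates = rates,
                   true_per_read_rate = inj$true_per_read_rate,
                   n_error_reads = inj$n_error_reads,
                   model = model, target_rate = target_rate, seed = seed),
              class = "shadow_sim")
  })
}

#' @export
print.shadow_sim <- function(x, ...) {
  cat("Simulated sequencing dataset (", x$model, " error model)\n", sep = "")
  cat(sprintf("  genome %s bp, %s reads of %d bp\n",
              format(nchar(x$reference), big.mark = ","),
              format(x$observed_reads$total_reads, big.mark = ","),
              x$clean_reads$read_length))
  cat(sprintf("  polymorphic sites: %d\n", nrow(x$polymorphism_sites)))
  cat(sprintf("  target per-read rate %.4g, realized %.4g\n",
              x$target_rate, x$true_per_read_rate))
  invisible(x)
}
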