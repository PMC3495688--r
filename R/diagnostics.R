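#' Select the most frequent reads
#'
#' Returns the `k` highest-count sequences of a table (all of them if fewer
#' than `k`), the regression points of the shadow fit. Deterministic under
#' ties: equal counts are ordered lexicographically by sequence, so the result
#' does not depend on input order.
#'
#' @param table a `read_count_table`.
#' @param k number of reads to select.
#' @return Character vector of sequences, ordered by decreasing count.
#' @export
select_top_reads <- function(table, k = 1000) {
  stopifnot(inherits(table, "read_count_table"))
  if (length(table$sequences) == 0) stop("empty read table")
  ord <- order(-table$counts, table$sequences, method = "radix")
  table$sequences[head(ord, k)]
}

#' Coverage-adequacy diagnostic
#'
#' Shadow regression needs leverage in the regression points: the top-k read
#' counts should spread over a range of roughly 500 or more, which requires
#' the maximum read count to reach roughly 500. This check reports both
#' quantities and whether they clear the (configurable) thresholds. Failure is
#' a warning sign, not a hard error: estimates from inadequate coverage are
#' simply unstable.
#'
#' @param table a `read_count_table`.
#' @param k top-read window, as used in the regression.
#' @param min_max,min_range adequacy thresholds on the maximum count and on
#'   the count range within the top k.
#' @return A list with `max_count`, `count_range`, `adequate`, and the
#'   thresholds used.
#' @export
coverage_adequacy <- function(table, k = 1000, min_max = 500, min_range = 500) {
  stopifnot(inherits(table, "read_count_table"))
  if (length(table$counts) == 0)
    return(list(max_count = 0, count_range = 0, adequate = FALSE,
                min_max = min_max, min_range = min_range))
  topc <- sort(table$counts, decreasing = TRUE)
  topc <- head(topc, k)
  mx <- max(topc)
  rng <- mx - min(topc)
  list(max_count = mx, count_range = rng,
       adequate = (mx >= min_max) && (rng >= min_range),
       min_max = min_max, min_range = min_range)
}

#' Repetitive-genome diagnostic
#'
#' Repetitive genomes produce abundant legitimate shadows — genuinely distinct
#' reads within an edit or two of each other — which inflate shadow-regression
#' estimates. The diagnostic samples error-free reads uniformly from a
#' candidate reference and runs the estimator: a result materially above zero
#' means the genome is too repetitive to apply the method directly (reads from
#' repetitive regions should then be masked out first).
#'
#' @param reference reference sequence: a single string, a
#'   `Biostrings::DNAStringSet`/`DNAString`, or a path to a FASTA file (the
#'   first sequence is used).
#' @param read_length length of sampled reads.
#' @param n_reads number of error-free reads to sample.
#' @param seed optional RNG seed for reproducibility.
#' @param threshold estimates above this flag the genome as repetitive.
#' @param top_k,max_dist passed to [shadow_regression()].
#' @return An object of class `repetitiveness_test`: list with `estimate`,
#'   `repetitive`, `threshold`, `read_length`, `n_reads`.
#' @export
repetitiveness_test <- function(reference, read_length = 36, n_reads = 2e5,
                                seed = NULL, threshold = 0.005,
                                top_k = 1000, max_dist = 2) {
  genome <- resolve_reference(reference)
  if (nchar(genome) <= read_length)
    stop("reference (length ", nchar(genome),
         ") must be longer than the read length")
  tab <- with_seed(seed, sample_clean_reads(genome, read_length, n_reads,
                                            abundance = "uniform"))
  est <- suppressWarnings(
    shadow_regression(tab, error_type = "substitution", top_k = top_k,
                      max_dist = max_dist, per_position = FALSE,
                      adequacy_warn = FALSE))
  structure(list(estimate = est$error_rate, repetitive = est$error_rate > threshold,
                 threshold = threshold, read_length = read_length,
                 n_reads = n_reads, fit = est),
            class = "repetitiveness_test")
}

#' @export
print.repetitiveness_test <- function(x, ...) {
  cat("Repetitive-genome diagnostic\n")
  cat(sprintf("  error-free sampling estimate: %.5f (threshold %.4g)\n",
              x$estimate, x$threshold))
  cat("  verdict:", if (x$repetitive)
    "REPETITIVE - shadow regression would be biased upward on this genome"
    else "not repetitive - shadow regression applicable", "\n")
  invisible(x)
}

resolve_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet") || inherits(reference, "BStringSet"))
    return(toupper(as.character(reference[[1]])))
  if (inherits(reference, "DNAString") || inherits(reference, "BString"))
    return(toupper(as.character(reference)))
  if (is.character(reference) && length(reference) == 1) {
    if (file.exists(reference) && grepl("\\.(fa|fasta|fna)(\\.gz)?$", reference,
                                        ignore.case = TRUE)) {
      ss <- Biostrings::readDNAStringSet(reference)
      if (length(ss) == 0) stop("no sequences in FASTA file ", reference)
      return(toupper(as.character(ss[[1]])))
    }
    return(toupper(reference))
  }
  stop("reference must be a sequence string, DNAString(Set), or FASTA path")
}
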