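#' Classify reads by minimal mismatch count against a reference
#'
#' The mismatch-counting comparator. Every read (weighted by its count) is
#' assigned the minimal Hamming distance over all alignment offsets of the
#' reference (and, optionally, the reverse-complement strand). Reads whose
#' best distance is 0, 1 or 2 *and* achieved at a unique offset increment
#' `u0`, `u1`, `u2`; a tie at the best distance (including a forward/reverse
#' tie) makes the read non-unique, and it is dropped from the tally; best
#' distance above 2 counts as unmatched. Mismatch read-positions of unique
#' best alignments accumulate into `per_position_mismatches`.
#'
#' The classification is exactly equivalent to a brute-force scan of all
#' offsets; a pigeonhole seed index merely accelerates it.
#'
#' @param table a `read_count_table`.
#' @param reference reference sequence (string, `DNAString(Set)`, or FASTA
#'   path).
#' @param both_strands also scan the reverse-complement strand.
#' @param circular treat the reference as circular (wrap-around offsets), as
#'   for small phage genomes.
#' @return An object of class `mismatch_tally`: `u0`, `u1`, `u2`, `unmatched`,
#'   `nonunique`, `per_position_mismatches`, `read_length`.
#' @examples
#' tab <- as_read_count_table(c(ACGTA = 3))
#' classify_reads(tab, "ACGTACGTAC")$u0  # 3
#' @export
classify_reads <- function(table, reference, both_strands = FALSE,
                           circular = FALSE) {
  stopifnot(inherits(table, "read_count_table"))
  genome <- resolve_reference(reference)
  L <- table$read_length
  if (nchar(genome) < L)
    stop("reference (length ", nchar(genome),
         ") is shorter than the read length (", L, ")")
  res <- cpp_classify_reads(table$sequences, table$counts, genome, L,
                            both_strands, circular, 2L)
  structure(list(u0 = res$u0, u1 = res$u1, u2 = res$u2,
                 unmatched = res$unmatched, nonunique = res$nonunique,
                 per_position_mismatches = as.numeric(res$per_position),
                 read_length = L,
                 n_classified = res$u0 + res$u1 + res$u2 + res$unmatched),
            class = "mismatch_tally")
}

#' @export
print.mismatch_tally <- function(x, ...) {
  cat("Mismatch tally against reference\n")
  cat(sprintf("  u0 %s   u1 %s   u2 %s   unmatched %s   non-unique (dropped) %s\n",
              format(x$u0), format(x$u1), format(x$u2),
              format(x$unmatched), format(x$nonunique)))
  if (x$u0 + x$u1 + x$u2 > 0)
    cat(sprintf("  mismatch-counting error rate: %.4f\n", mismatch_error_rate(x)))
  invisible(x)
}

#' Mismatch-counting error-rate estimate
#'
#' Estimates the per-read error rate as `(u1 + u2) / (u0 + u1 + u2)`: the
#' fraction of uniquely mapped reads that needed one or two mismatches. This
#' assumes the mismatches are sequencing errors; genuine sample-reference
#' differences (polymorphisms, mutations) are counted as errors too, which
#' biases the estimate upward.
#'
#' @param tally a `mismatch_tally` from [classify_reads()].
#' @return Per-read error rate in `[0, 1]`.
#' @seealso [per_position_mismatch_rates()] for the positional analogue.
#' @export
mismatch_error_rate <- function(tally) {
  stopifnot(inherits(tally, "mismatch_tally"))
  denom <- tally$u0 + tally$u1 + tally$u2
  if (denom == 0) stop("no uniquely mapped reads with <= 2 mismatches")
  (tally$u1 + tally$u2) / denom
}

#' @rdname mismatch_error_rate
#' @export
per_position_mismatch_rates <- function(tally) {
  stopifnot(inherits(tally, "mismatch_tally"))
  denom <- tally$u0 + tally$u1 + tally$u2
  if (denom == 0) stop("no uniquely mapped reads with <= 2 mismatches")
  tally$per_position_mismatches / denom
}

#' Unmatched-tag error fraction from match counts
#'
#' The classical tag-library error estimate: tags in a sequenced library that
#' match no known source sequence are attributed to sequencing error. Given
#' the library total and the counts matched to each source, the remainder is
#' the unmatched count and its percentage of the library is the error
#' fraction.
#'
#' @param total total number of tags in the library.
#' @param matched_counts counts matched to each source (e.g. nuclear genome,
#'   mitochondrial genome, plasmid).
#' @return A list with `unmatched` (count) and `fraction` (percent of
#'   `total`, truncated to one decimal — the convention of the published
#'   library breakdowns, which never round an error fraction up).
#' @examples
#' error_fraction_from_match_counts(60633, c(56291, 88, 91))
#' # unmatched 4163, fraction 6.8
#' @export
error_fraction_from_match_counts <- function(total, matched_counts) {
  stopifnot(is.numeric(total), length(total) == 1, is.numeric(matched_counts))
  unmatched <- total - sum(matched_counts)
  if (unmatched < 0)
    stop("matched counts (", sum(matched_counts), ") exceed the total (", total, ")")
  list(unmatched = unmatched,
       fraction = floor(1000 * unmatched / total) / 10)
}
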