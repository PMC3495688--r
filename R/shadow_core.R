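#' Shadow neighborhoods of a read
#'
#' Enumerate all length-preserving sequences within `max_dist` edits of a read,
#' for a given error type. These are the candidate "shadows" of the read: the
#' sequences a copy of the read can turn into through one or two errors.
#'
#' * `substitution_neighbors()`: all sequences at Hamming distance 1..`max_dist`.
#'   The set has size `3L` at distance 1 and `3L + 9*choose(L,2)` up to
#'   distance 2.
#' * `insertion_neighbors()`: fixed-length insertion shadows. For each position
#'   p and base b, b is inserted before p and the displaced 3' terminal base is
#'   dropped, keeping the read length constant (an insertion during sequencing
#'   shifts the remaining template out of the read).
#' * `deletion_neighbors()`: fixed-length deletion shadows. Base p is removed
#'   and each of the four bases is appended at the 3' end, standing for the
#'   unknown next template base.
#'
#' For `max_dist = 2` the generative rule is applied twice. The read itself is
#' never a member of its own neighborhood and duplicates are removed.
#'
#' @param seq a read sequence over A/C/G/T.
#' @param max_dist maximum edit distance, 1 or 2.
#' @return Sorted character vector of neighbor sequences, all of length
#'   `nchar(seq)`.
#' @examples
#' length(substitution_neighbors("ACGT", 1))  # 12
#' length(substitution_neighbors("ACGT", 2))  # 66
#' @export
substitution_neighbors <- function(seq, max_dist = 2) {
  check_neighbor_args(seq, max_dist)
  sort(cpp_neighbors(seq, "substitution", as.integer(max_dist)))
}

#' @rdname substitution_neighbors
#' @export
insertion_neighbors <- function(seq, max_dist = 2) {
  check_neighbor_args(seq, max_dist)
  sort(cpp_neighbors(seq, "insertion", as.integer(max_dist)))
}

#' @rdname substitution_neighbors
#' @export
deletion_neighbors <- function(seq, max_dist = 2) {
  check_neighbor_args(seq, max_dist)
  sort(cpp_neighbors(seq, "deletion", as.integer(max_dist)))
}

check_neighbor_args <- function(seq, max_dist) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) < 1)
    stop("seq must be a single non-empty sequence string")
  if (grepl("[^ACGT]", seq)) stop("seq must contain only A/C/G/T")
  if (!max_dist %in% c(1, 2))
    stop("max_dist must be 1 or 2 (larger neighborhoods are not supported)")
  if (nchar(seq) < max_dist) stop("seq shorter than max_dist")
  invisible(TRUE)
}

#' Shadow profile of a target read
#'
#' Counts the observed shadows of a target read in a read-count table: the
#' total count of table entries lying in the target's neighborhood
#' (`shadow_total`, the regression response s_t) and the position-stratified
#' counts `shadow_by_position`, where entry i sums the counts of shadows that
#' differ from the target at least at position i. A distance-2 substitution
#' shadow therefore contributes to both of its differing positions; indel
#' shadows credit their edit position(s). Reads in `exclude` (normally the
#' top-k high-frequency reads, regarded as error free) are never counted as
#' shadows.
#'
#' @param table a `read_count_table`.
#' @param target a read sequence present in `table`.
#' @param exclude character vector of sequences excluded from shadow counts.
#' @param error_type one of `"substitution"`, `"insertion"`, `"deletion"`.
#' @param max_dist maximum edit distance, 1 or 2.
#' @return An object of class `shadow_profile`: list with `target`,
#'   `target_count`, `shadow_total`, `shadow_by_position`, `error_type`.
#' @examples
#' tab <- as_read_count_table(c(AAAA = 100, AAAT = 5, AATT = 2, CCCC = 50))
#' shadow_profile(tab, "AAAA", exclude = c("AAAA", "CCCC"))
#' @export
shadow_profile <- function(table, target, exclude = character(),
                           error_type = c("substitution", "insertion", "deletion"),
                           max_dist = 2) {
  stopifnot(inherits(table, "read_count_table"))
  error_type <- match.arg(error_type)
  idx <- match(target, table$sequences)
  if (is.na(idx)) stop("target read not present in table: ", target)
  res <- cpp_shadow_profiles(target, table$sequences, table$counts,
                             as.character(exclude), error_type,
                             as.integer(max_dist))
  structure(list(target = target,
                 target_count = table$counts[idx],
                 shadow_total = res$total[1],
                 shadow_by_position = as.numeric(res$by_position[1, ]),
                 error_type = error_type,
                 max_dist = max_dist),
            class = "shadow_profile")
}

#' @export
print.shadow_profile <- function(x, ...) {
  cat("Shadow profile (", x$error_type, ", max_dist ", x$max_dist, ")\n", sep = "")
  cat("  target:", x$target, " count:", x$target_count, "\n")
  cat("  shadow total:", x$shadow_total, "\n")
  cat("  by position:", paste(x$shadow_by_position, collapse = " "), "\n")
  invisible(x)
}

# Vectorised profile computation over many targets; returns list(total, by_position).
shadow_profiles_matrix <- function(table, targets, exclude, error_type, max_dist) {
  cpp_shadow_profiles(targets, table$sequences, table$counts,
                      as.character(exclude), error_type, as.integer(max_dist))
}
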