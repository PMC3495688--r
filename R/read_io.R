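#' Read-count tables
#'
#' A `read_count_table` holds the observed unique read sequences of a sample
#' together with their counts. All retained sequences have the same length and
#' contain only A/C/G/T. `n_filtered` records how many raw reads (or, for
#' tag-count input, how much total count) was removed by the filters: reads
#' containing any no-call or ambiguity character, and single-letter
#' homopolymers, are discarded.
#'
#' @param x a named numeric vector (names = sequences, values = counts) or a
#'   data frame with columns `sequence` and `count`.
#' @param n_filtered count of reads removed by filtering before `x` was built.
#' @return An object of class `read_count_table` with fields `sequences`,
#'   `counts`, `read_length`, `total_reads` and `n_filtered`.
#' @examples
#' as_read_count_table(c(ACGT = 10, ACGA = 2))
#' @export
as_read_count_table <- function(x, n_filtered = 0L) {
  if (is.data.frame(x)) {
    seqs <- as.character(x$sequence)
    counts <- as.numeric(x$count)
  } else {
    seqs <- names(x)
    counts <- as.numeric(x)
  }
  new_read_count_table(seqs, counts, n_filtered = n_filtered)
}

# Internal constructor; consolidates duplicates, validates invariants.
new_read_count_table <- function(seqs, counts, n_filtered = 0L, sort_seqs = TRUE) {
  stopifnot(length(seqs) == length(counts))
  seqs <- unname(seqs)
  counts <- unname(counts)
  if (length(seqs) > 0) {
    if (anyDuplicated(seqs)) {
      agg <- rowsum(counts, group = seqs)
      seqs <- rownames(agg)
      counts <- as.numeric(agg)
    } else if (sort_seqs) {
      ord <- order(seqs, method = "radix")
      seqs <- seqs[ord]
      counts <- counts[ord]
    }
    if (any(counts < 1)) stop("all read counts must be >= 1")
    lens <- unique(nchar(seqs))
    if (length(lens) != 1)
      stop("mixed read lengths among retained reads (", paste(lens, collapse = ", "),
           "); all reads in a sample must have the same length")
    if (any(grepl("[^ACGT]", seqs)))
      stop("sequences must contain only A/C/G/T after filtering")
    read_length <- lens
  } else {
    read_length <- 0L
  }
  structure(list(sequences = seqs, counts = counts,
                 read_length = as.integer(read_length),
                 total_reads = sum(counts),
                 n_filtered = as.numeric(n_filtered)),
            class = "read_count_table")
}

#' @export
print.read_count_table <- function(x, ...) {
  cat("Read-count table:", length(x$sequences), "unique sequences,",
      format(x$total_reads, big.mark = ","), "total reads\n")
  cat("  read length:", x$read_length, "  filtered out:", x$n_filtered, "\n")
  if (length(x$sequences) > 0) {
    ord <- order(-x$counts, x$sequences)
    k <- head(ord, 5)
    cat("  top counts:\n")
    for (i in k) cat("   ", x$sequences[i], x$counts[i], "\n")
  }
  invisible(x)
}

#' Read-retention filter
#'
#' Decides which reads enter the analysis. A read is discarded if it contains
#' any character other than A, C, G or T (no-calls and IUPAC ambiguity codes
#' are all treated as no-calls), or if it is a single-letter homopolymer
#' (all A's, C's, G's or T's). Case-insensitive.
#'
#' @param seqs character vector of read sequences.
#' @return Logical vector, `TRUE` where the read is kept.
#' @examples
#' filter_reads(c("ACGT", "ACGN", "TTTT"))  # TRUE FALSE FALSE
#' @export
filter_reads <- function(seqs) {
  seqs <- toupper(seqs)
  ok <- grepl("^[ACGT]+$", seqs)
  homo <- seqs == strrep(substr(seqs, 1, 1), nchar(seqs))
  ok & !homo
}

# Build a table from a raw character vector of reads, applying the filters.
table_from_reads <- function(reads, prefiltered = FALSE) {
  reads <- toupper(reads)
  if (prefiltered) {
    kept <- reads
    nf <- 0
  } else {
    keep <- filter_reads(reads)
    kept <- reads[keep]
    nf <- sum(!keep)
  }
  if (length(kept) == 0) return(new_read_count_table(character(), numeric(), n_filtered = nf))
  r <- rle(sort(kept, method = "radix"))
  new_read_count_table(r$values, r$lengths, n_filtered = nf, sort_seqs = FALSE)
}

#' Read a FASTQ file into a read-count table
#'
#' Reads a (optionally gzipped) FASTQ file, applies the retention filters of
#' [filter_reads()] and tabulates counts of the unique retained sequences.
#' Quality strings are ignored: the shadow method uses sequence content only.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @param max_reads optional cap on the number of records read.
#' @param trim_to optional read length to truncate every read to (3' trimming);
#'   by default reads are used at full length and mixed lengths are an error.
#' @return A [read_count_table][as_read_count_table].
#' @export
read_fastq <- function(path, max_reads = NULL, trim_to = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  nrec <- if (is.null(max_reads)) -1L else as.integer(max_reads)
  ss <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", nrec = nrec),
    error = function(e) {
      idx <- locate_bad_fastq_record(path)
      if (!is.na(idx))
        stop("malformed FASTQ record at record ", idx, " in ", path, call. = FALSE)
      stop("failed to parse FASTQ file ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  reads <- as.character(ss)
  if (!is.null(trim_to)) reads <- substr(reads, 1L, as.integer(trim_to))
  table_from_reads(reads)
}

# Cheap scan for the first structurally broken 4-line FASTQ record.
locate_bad_fastq_record <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  i <- 0L
  repeat {
    block <- readLines(con, n = 4L)
    if (length(block) == 0) return(NA_integer_)
    i <- i + 1L
    if (length(block) < 4L) return(i)
    if (!startsWith(block[1], "@") || !startsWith(block[3], "+")) return(i)
    if (nchar(block[2]) != nchar(block[4])) return(i)
  }
}

#' Read a tag/read count table
#'
#' Reads a two-column whitespace- or tab-delimited text file of
#' `sequence count` rows (the SAGE distribution format), applies the retention
#' filters and returns a [read_count_table][as_read_count_table]. Lines
#' starting with `#` are skipped; duplicated sequences have their counts
#' summed with a warning.
#'
#' @param path path to the count file.
#' @return A `read_count_table`.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- read.table(path, header = FALSE, comment.char = "#",
                   colClasses = c("character", "character"),
                   col.names = c("sequence", "count"))
  if (nrow(df) == 0) return(new_read_count_table(character(), numeric()))
  counts <- suppressWarnings(as.numeric(df$count))
  if (any(is.na(counts)) || any(counts != floor(counts)) || any(counts <= 0))
    stop("counts must be positive integers (offending rows: ",
         paste(head(which(is.na(counts) | counts <= 0 | counts != floor(counts)), 3),
               collapse = ", "), ")")
  seqs <- toupper(df$sequence)
  if (anyDuplicated(seqs))
    warning("duplicate sequence rows in ", path, "; counts summed")
  keep <- filter_reads(seqs)
  nf <- sum(counts[!keep])
  new_read_count_table(seqs[keep], counts[keep], n_filtered = nf)
}

#' Write a read-count table as TSV
#'
#' @param table a `read_count_table`.
#' @param path output path. Columns: sequence, count; no header.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "read_count_table"))
  df <- data.frame(sequence = table$sequences, count = table$counts)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' Expands a read-count table to one record per read copy (or writes a raw
#' character vector of reads) with constant dummy qualities, for interchange
#' with external tools.
#'
#' @param reads a `read_count_table` or character vector of read sequences.
#' @param path output path; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "read_count_table"))
    reads <- rep(reads$sequences, times = reads$counts)
  n <- length(reads)
  qual <- strrep("I", nchar(reads))
  lines <- character(4 * n)
  lines[seq(1, length.out = n, by = 4)] <- paste0("@read", seq_len(n))
  lines[seq(2, length.out = n, by = 4)] <- reads
  lines[seq(3, length.out = n, by = 4)] <- "+"
  lines[seq(4, length.out = n, by = 4)] <- qual
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
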