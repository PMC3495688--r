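# Independent oracles used to validate the fast implementations.

BASES <- c("A", "C", "G", "T")

# All 4^L strings of length L (L small).
all_kmers <- function(L) {
  grid <- expand.grid(rep(list(BASES), L), stringsAsFactors = FALSE)
  do.call(paste0, rev(grid))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Substitution neighbors by exhaustive scan over the full k-mer space.
brute_sub_neighbors <- function(seq, max_dist) {
  L <- nchar(seq)
  ks <- all_kmers(L)
  tchars <- strsplit(seq, "")[[1]]
  m <- matrix(unlist(strsplit(ks, ""), use.names = FALSE), nrow = L)
  d <- colSums(m != tchars)
  sort(ks[d >= 1 & d <= max_dist])
}

# Generative indel rules, applied naively with R string ops.
ins_once <- function(seq) {
  L <- nchar(seq)
  out <- character()
  for (p in seq_len(L)) for (b in BASES) {
    v <- paste0(substr(seq, 1, p - 1), b, substr(seq, p, L))
    out <- c(out, substr(v, 1, L))
  }
  unique(out)
}

del_once <- function(seq) {
  L <- nchar(seq)
  out <- character()
  for (p in seq_len(L)) for (b in BASES) {
    out <- c(out, paste0(substr(seq, 1, p - 1), substr(seq, p + 1, L), b))
  }
  unique(out)
}

brute_indel_neighbors <- function(seq, max_dist, insertion) {
  once <- if (insertion) ins_once else del_once
  d1 <- setdiff(once(seq), seq)
  res <- d1
  if (max_dist >= 2) {
    d2 <- unique(unlist(lapply(d1, once)))
    res <- union(res, setdiff(d2, seq))
  }
  sort(res)
}

# Brute-force all-offsets Hamming classification of one read (count 1).
# Returns list(dist, n_best) with dist = minimal distance (Inf if > max_mm).
brute_classify_one <- function(read, ref, both_strands = FALSE,
                               circular = FALSE, max_mm = 2) {
  L <- nchar(read)
  n <- nchar(ref)
  ext <- if (circular) paste0(ref, substr(ref, 1, L - 1)) else ref
  offs <- if (circular) seq_len(n) else seq_len(n - L + 1)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  reads <- if (both_strands) c(read, rc(read)) else read
  best <- Inf
  nbest <- 0
  for (rd in reads) for (o in offs) {
    d <- hamming(rd, substr(ext, o, o + L - 1))
    if (d < best) {
      best <- d
      nbest <- 1
    } else if (d == best) nbest <- nbest + 1
  }
  if (best > max_mm) list(dist = Inf, n_best = 0)
  else list(dist = best, n_best = nbest)
}

# Engineered repetitive genome: n_copies of one unit, each with a few private
# substitutions, concatenated. Guarantees abundant legitimate shadows.
make_repetitive_genome <- function(seed, n_copies = 500, unit_len = 200,
                                   snps_per_copy = 2) {
  set.seed(seed)
  unit <- strsplit(generate_reference(unit_len), "")[[1]]
  copies <- vapply(seq_len(n_copies), function(i) {
    u <- unit
    for (p in sample(unit_len, snps_per_copy))
      u[p] <- sample(setdiff(BASES, u[p]), 1)
    paste(u, collapse = "")
  }, "")
  paste(copies, collapse = "")
}

# Write a 4-line FASTQ file from sequences (constant dummy quality).
write_tmp_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  lines <- as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                           strrep("I", nchar(seqs))))
  writeLines(lines, path)
  path
}
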