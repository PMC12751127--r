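# Independent R-level oracles, deliberately naive: matching is checked
# against these brute-force implementations, never against itself.

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(!(ca == cb & ca != "N"))
}

# Levenshtein via base adist; valid oracle on N-free sequences.
oracle_levenshtein <- function(a, b) as.integer(utils::adist(a, b))

oracle_similarity <- function(q, r)
  max(0, 1 - oracle_levenshtein(q, r) / nchar(r))

# All-pairs scan: one row per query with n_hits / status / ref_index.
oracle_match <- function(seqs, refs, metric, cutoff) {
  t(vapply(seqs, function(s) {
    hit <- vapply(refs, function(r) {
      if (metric == "hamming") {
        nchar(s) == nchar(r) && oracle_hamming(s, r) <= cutoff
      } else {
        oracle_similarity(s, r) >= cutoff
      }
    }, logical(1))
    n <- sum(hit)
    c(n_hits = n, ref_index = if (n == 1L) which(hit) else NA_integer_)
  }, c(n_hits = NA_integer_, ref_index = NA_integer_)))
}

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# Substitute exactly n distinct positions of seq with a different base.
substitute_bases <- function(seq, n) {
  pos <- sample.int(nchar(seq), n)
  for (p in pos) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  seq
}

write_tiny_fastq <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("F", nchar(seqs))), con)
  close(con)
  path
}
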