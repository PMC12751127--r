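#' Hamming distance between two equal-length sequences
#'
#' Counts mismatching positions. `N` is treated as unknown and never
#' matches any base, including another `N`.
#'
#' @param a,b Sequences of equal length.
#' @return Integer distance.
#' @examples
#' hamming_distance("ACGT", "ACGA") # 1
#' hamming_distance("ANGT", "ANGT") # 2: N never matches
#' @export
hamming_distance <- function(a, b) .hamming_distance_cpp(a, b)

#' Normalized edit-distance similarity
#'
#' `1 - levenshtein(query, ref) / nchar(ref)`, floored at 0. One
#' substitution on a 16-mer scores `1 - 1/16 = 0.9375`, which clears the
#' default tag cutoff of 0.93; two substitutions score 0.875 and fail it.
#' `N` never matches any base.
#'
#' @param query,ref Non-empty sequences; `ref` sets the denominator.
#' @return Similarity in `[0, 1]`.
#' @export
normalized_similarity <- function(query, ref) {
  if (!nzchar(ref)) stop("reference sequence must be non-empty")
  if (!nzchar(query)) stop("query sequence must be non-empty")
  max(0, 1 - .levenshtein_distance_cpp(query, ref) / nchar(ref))
}

#' Assign one sequence to at most one reference entry
#'
#' Counts the references meeting the cutoff (`hamming`: distance <=
#' `cell_max_mismatch`; `ratio`: similarity >= `oligo_min_ratio`). The
#' assignment is `unique` only when exactly one reference qualifies;
#' two or more qualifying references make the read `ambiguous` and it is
#' dropped with no best-score rescue; zero make it `none`. Under the
#' `hamming` metric a query whose length differs from a reference cannot
#' hit it.
#'
#' @param seq A sequence.
#' @param refs An [oligo_reference()], [cell_whitelist()], or character
#'   vector of reference sequences.
#' @param metric `"hamming"` or `"ratio"`.
#' @param params A [match_params()].
#' @return List with `status` (`"unique"`, `"none"`, `"ambiguous"`),
#'   `ref_index` (1-based, `NA` unless unique) and `n_hits`.
#' @export
match_one <- function(seq, refs, metric = c("hamming", "ratio"),
                      params = match_params()) {
  res <- match_batch(seq, refs, metric, params)
  list(status = res$status[[1]], ref_index = res$ref_index[[1]],
       n_hits = res$n_hits[[1]])
}

ref_seqs <- function(refs) {
  if (inherits(refs, "oligo_reference")) refs$sequence
  else if (inherits(refs, "cell_whitelist")) as.character(unclass(refs))
  else if (is.character(refs)) refs
  else stop("refs must be an oligo_reference, cell_whitelist or character")
}

#' Assign a batch of sequences to references, in chunks
#'
#' Elementwise identical to [match_one()] over `seqs`; the result is
#' bit-identical for any `chunk_size` or `threads` setting. Chunking keeps
#' the all-pairs distance computation within memory bounds on large runs.
#'
#' @param seqs Character vector of sequences.
#' @param refs Reference list as in [match_one()].
#' @param metric `"hamming"` or `"ratio"`.
#' @param params A [match_params()].
#' @return data.frame with columns `status`, `ref_index`, `n_hits`,
#'   one row per input sequence.
#' @export
match_batch <- function(seqs, refs, metric = c("hamming", "ratio"),
                        params = match_params()) {
  metric <- match.arg(metric)
  rs <- ref_seqs(refs)
  if (length(rs) == 0L) stop("empty reference list")
  seqs <- as.character(seqs)
  empty <- data.frame(status = character(), ref_index = integer(),
                      n_hits = integer(), stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(empty)

  starts <- seq(1L, length(seqs), by = params$chunk_size)
  chunks <- lapply(starts, function(s)
    seqs[s:min(s + params$chunk_size - 1L, length(seqs))])
  worker <- function(chunk) {
    if (metric == "hamming")
      .match_hamming_cpp(chunk, rs, params$cell_max_mismatch)
    else
      .match_ratio_cpp(chunk, rs, params$oligo_min_ratio)
  }
  parts <- if (params$threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(chunks, worker, mc.cores = params$threads)
  } else {
    lapply(chunks, worker)
  }
  n_hits <- unlist(lapply(parts, `[[`, "n_hits"))
  ref_index <- unlist(lapply(parts, `[[`, "hit_index"))
  status <- ifelse(n_hits == 0L, "none",
                   ifelse(n_hits == 1L, "unique", "ambiguous"))
  data.frame(status = status, ref_index = ref_index, n_hits = n_hits,
             stringsAsFactors = FALSE)
}
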