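#' Read layout: where the barcode, UMI and tag live inside each read
#'
#' Describes the fixed windows extracted from the two reads of a pair. All
#' offsets are 0-based; windows are half-open `[start, start + len)`. The
#' defaults match the prevailing droplet chemistry: a 16-bp cell barcode
#' followed by a 12-bp UMI on the cell-ID read, and a 16-bp tag at the start
#' of the oligo read.
#'
#' @param barcode_start 0-based offset of the cell barcode in the cell-ID read.
#' @param barcode_len Cell-barcode length in bases.
#' @param umi_start 0-based offset of the UMI in the cell-ID read.
#' @param umi_len UMI length in bases.
#' @param tag_start 0-based offset of the tag in the oligo read.
#' @param tag_len Tag length in bases; must equal the oligo reference width
#'   when Hamming-style comparison is used.
#' @return A `read_layout` object (named list).
#' @examples
#' read_layout()
#' read_layout(umi_len = 10)
#' @export
read_layout <- function(barcode_start = 0L, barcode_len = 16L,
                        umi_start = 16L, umi_len = 12L,
                        tag_start = 0L, tag_len = 16L) {
  vals <- c(barcode_start = barcode_start, barcode_len = barcode_len,
            umi_start = umi_start, umi_len = umi_len,
            tag_start = tag_start, tag_len = tag_len)
  if (any(vals < 0)) stop("layout offsets and lengths must be >= 0")
  if (any(vals[c("barcode_len", "umi_len", "tag_len")] < 1))
    stop("barcode_len, umi_len and tag_len must be >= 1")
  bc <- c(barcode_start, barcode_start + barcode_len)
  um <- c(umi_start, umi_start + umi_len)
  if (max(bc[1], um[1]) < min(bc[2], um[2]))
    stop("barcode and UMI windows overlap in the cell-ID read")
  structure(as.list(as.integer(vals)), names = names(vals),
            class = "read_layout")
}

#' Matching parameters
#'
#' Cutoffs and batching controls for assigning sequences to references.
#' Cell barcodes are accepted within `cell_max_mismatch` Hamming mismatches
#' of a whitelist entry (default 1); tags are accepted when the normalized
#' edit-distance similarity `1 - levenshtein/len(ref)` reaches
#' `oligo_min_ratio` (default 0.93, i.e. one mismatch on a 16-bp tag, which
#' scores 0.9375). Sequences meeting the cutoff for two or more references
#' are ambiguous and dropped. Batches are processed in chunks of
#' `chunk_size` sequences, optionally across `threads` forked workers;
#' results are identical for any chunking or thread count.
#'
#' @param cell_max_mismatch Hamming cutoff for cell barcodes.
#' @param oligo_min_ratio Similarity cutoff in `[0, 1]` for tags.
#' @param chunk_size Sequences per processing chunk.
#' @param threads Forked worker count (1 = serial; forking is unavailable on
#'   Windows, where matching falls back to serial).
#' @return A `match_params` object.
#' @export
match_params <- function(cell_max_mismatch = 1L, oligo_min_ratio = 0.93,
                         chunk_size = 100000L, threads = 1L) {
  if (cell_max_mismatch < 0) stop("cell_max_mismatch must be >= 0")
  if (oligo_min_ratio < 0 || oligo_min_ratio > 1)
    stop("oligo_min_ratio must be in [0, 1]")
  if (chunk_size < 1) stop("chunk_size must be >= 1")
  if (threads < 1) stop("threads must be >= 1")
  structure(list(cell_max_mismatch = as.integer(cell_max_mismatch),
                 oligo_min_ratio = as.numeric(oligo_min_ratio),
                 chunk_size = as.integer(chunk_size),
                 threads = as.integer(threads)),
            class = "match_params")
}

#' UMI deduplication parameters
#'
#' `mode = "exact"` (the default) collapses reads sharing an identical key;
#' `mode = "fuzzy"` additionally merges UMIs within `umi_max_mismatch`
#' Hamming mismatches via connected components. The key is `(cell, UMI)` by
#' default (`key_scope = "cell_umi"`); `"cell_oligo_umi"` also separates by
#' assigned oligo, the convention of most feature-barcode pipelines.
#'
#' @param mode `"exact"` or `"fuzzy"`.
#' @param umi_max_mismatch Hamming radius for fuzzy UMI merging (>= 1).
#' @param key_scope `"cell_umi"` or `"cell_oligo_umi"`.
#' @return A `dedup_params` object.
#' @export
dedup_params <- function(mode = c("exact", "fuzzy"), umi_max_mismatch = 1L,
                         key_scope = c("cell_umi", "cell_oligo_umi")) {
  mode <- match.arg(mode)
  key_scope <- match.arg(key_scope)
  if (mode == "fuzzy" && umi_max_mismatch < 1)
    stop("umi_max_mismatch must be >= 1 in fuzzy mode")
  structure(list(mode = mode,
                 umi_max_mismatch = as.integer(umi_max_mismatch),
                 key_scope = key_scope),
            class = "dedup_params")
}
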