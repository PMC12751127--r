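#' Read paired FASTQ lanes and extract barcode, UMI and tag windows
#'
#' Each lane is a pair of FASTQ files with matching record order: one file
#' holding the cell-ID read (barcode + UMI) and one holding the oligo read
#' (tag). Lanes are concatenated in the order given. Records too short for
#' any required window are counted and skipped, never truncated or padded.
#' Base qualities are ignored throughout.
#'
#' @param cellid_paths Character vector of cell-ID FASTQ paths (gz ok).
#' @param oligo_paths Character vector of oligo FASTQ paths, same length.
#' @param layout A [read_layout()].
#' @return A list with `reads` (data.frame: `read_id`, `cell_seq`,
#'   `umi_seq`, `tag_seq`), `reads_total` (records seen) and
#'   `reads_skipped_short`.
#' @export
read_paired_fastq <- function(cellid_paths, oligo_paths,
                              layout = read_layout()) {
  if (length(cellid_paths) != length(oligo_paths))
    stop("cellid_paths and oligo_paths must pair up lane by lane (",
         length(cellid_paths), " vs ", length(oligo_paths), ")")
  if (length(cellid_paths) == 0L) stop("no input FASTQ files given")

  need_cell <- max(layout$barcode_start + layout$barcode_len,
                   layout$umi_start + layout$umi_len)
  need_tag <- layout$tag_start + layout$tag_len

  lanes <- vector("list", length(cellid_paths))
  skipped <- 0L
  total <- 0L
  for (k in seq_along(cellid_paths)) {
    cell <- read_fastq_seqs(cellid_paths[[k]])
    olig <- read_fastq_seqs(oligo_paths[[k]])
    if (length(cell$seq) != length(olig$seq))
      stop("lane ", k, ": record counts differ between ",
           cellid_paths[[k]], " (", length(cell$seq), ") and ",
           oligo_paths[[k]], " (", length(olig$seq), ")")
    total <- total + length(cell$seq)
    ok <- nchar(cell$seq) >= need_cell & nchar(olig$seq) >= need_tag
    skipped <- skipped + sum(!ok)
    lanes[[k]] <- data.frame(
      read_id = cell$id[ok],
      cell_seq = substr(cell$seq[ok], layout$barcode_start + 1L,
                        layout$barcode_start + layout$barcode_len),
      umi_seq = substr(cell$seq[ok], layout$umi_start + 1L,
                       layout$umi_start + layout$umi_len),
      tag_seq = substr(olig$seq[ok], layout$tag_start + 1L,
                       layout$tag_start + layout$tag_len),
      stringsAsFactors = FALSE)
  }
  if (total == 0L) stop("input FASTQ files contain no records")
  list(reads = do.call(rbind, lanes),
       reads_total = total,
       reads_skipped_short = skipped)
}

# One FASTQ file -> list(id, seq) as character vectors, via Biostrings.
read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = FALSE),
    error = function(e) stop("unparseable FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  id <- sub("[ \t].*$", "", names(x))
  list(id = unname(id), seq = unname(toupper(as.character(x))))
}
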