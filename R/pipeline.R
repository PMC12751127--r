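#' Count antibody-derived tags: FASTQ pairs to deduplicated count matrix
#'
#' The end-to-end pipeline. For every read pair the barcode, UMI and tag
#' windows are extracted; the barcode is matched to the whitelist by
#' Hamming distance (cutoff `cell_max_mismatch`) and the tag to the oligo
#' panel by the normalized edit-distance ratio (cutoff `oligo_min_ratio`);
#' only reads with a unique hit on *both* sides are kept; UMI duplicates
#' are collapsed; each surviving molecule increments one matrix cell. The
#' matrix always spans the full panel-by-whitelist dimensions. Reads
#' hitting several whitelist barcodes or several oligos are ambiguous and
#' dropped; both tallies are reported.
#'
#' @param cellid_fastq Character vector of cell-ID FASTQ paths (lanes).
#' @param oligo_fastq Matching oligo FASTQ paths.
#' @param oligos An [oligo_reference()] or a path for
#'   [load_oligo_reference()].
#' @param whitelist A [cell_whitelist()] or a path for [load_whitelist()].
#' @param outdir Output directory; `NULL` skips all file output.
#' @param layout A [read_layout()].
#' @param match A [match_params()].
#' @param dedup A [dedup_params()].
#' @param csv_out If TRUE also write the dense CSV matrix.
#' @param verbose Print per-stage progress lines.
#' @return List with `matrix` ([count_matrix()]) and `report`
#'   (`run_report`).
#' @export
run_count <- function(cellid_fastq, oligo_fastq, oligos, whitelist,
                      outdir = NULL, layout = read_layout(),
                      match = match_params(), dedup = dedup_params(),
                      csv_out = FALSE, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.character(oligos) && !inherits(oligos, "oligo_reference"))
    oligos <- load_oligo_reference(oligos)
  if (is.character(whitelist) && !inherits(whitelist, "cell_whitelist"))
    whitelist <- load_whitelist(whitelist)
  if (!inherits(oligos, "oligo_reference"))
    stop("stage reference: oligos must be an oligo_reference or a path")
  if (!inherits(whitelist, "cell_whitelist"))
    stop("stage reference: whitelist must be a cell_whitelist or a path")

  say("reading FASTQ pairs")
  fq <- read_paired_fastq(cellid_fastq, oligo_fastq, layout)
  say("  ", fq$reads_total, " read pairs, ", fq$reads_skipped_short,
      " skipped (too short)")

  say("matching ", nrow(fq$reads), " barcodes and tags")
  cell_m <- match_batch(fq$reads$cell_seq, whitelist, "hamming", match)
  oligo_m <- match_batch(fq$reads$tag_seq, oligos, "ratio", match)
  both <- cell_m$status == "unique" & oligo_m$status == "unique"
  say("  cell: ", sum(cell_m$status == "unique"), " unique / ",
      sum(cell_m$status == "ambiguous"), " ambiguous; oligo: ",
      sum(oligo_m$status == "unique"), " unique / ",
      sum(oligo_m$status == "ambiguous"), " ambiguous")

  assigned <- assigned_reads(cell_m$ref_index[both],
                             oligo_m$ref_index[both],
                             fq$reads$umi_seq[both])
  say("deduplicating ", nrow(assigned), " assigned reads (",
      dedup$mode, ")")
  dd <- dedup_reads(assigned, dedup)
  surv <- dd$survivors

  mat <- count_matrix(
    Matrix::sparseMatrix(i = surv$oligo_index, j = surv$cell_index,
                         x = rep(1, nrow(surv)),
                         dims = c(nrow(oligos), length(whitelist))),
    features = oligos$name,
    barcodes = as.character(unclass(whitelist)))

  amb_cell_bc <- unique(fq$reads$cell_seq[cell_m$status == "ambiguous"])
  amb_oligo_tag <- unique(fq$reads$tag_seq[oligo_m$status == "ambiguous"])
  report <- structure(list(
    reads_total = fq$reads_total,
    reads_skipped_short = fq$reads_skipped_short,
    cell_unique = sum(cell_m$status == "unique"),
    cell_none = sum(cell_m$status == "none"),
    cell_ambiguous = sum(cell_m$status == "ambiguous"),
    cell_ambiguous_distinct = length(amb_cell_bc),
    oligo_unique = sum(oligo_m$status == "unique"),
    oligo_none = sum(oligo_m$status == "none"),
    oligo_ambiguous = sum(oligo_m$status == "ambiguous"),
    oligo_ambiguous_distinct = length(amb_oligo_tag),
    reads_assigned = sum(both),
    umi_duplicates_removed = dd$report$n_removed,
    reads_in_matrix = nrow(surv),
    dedup = dd$report,
    params = list(layout = layout, match = match, dedup = dedup)),
    class = "run_report")
  stopifnot(report$reads_in_matrix == sum(mat))

  if (!is.null(outdir)) {
    staging <- tempfile("adtcount_out_")
    dir.create(staging, recursive = TRUE)
    write_mtx_triplet(mat, staging)
    if (csv_out) write_dense_csv(mat, file.path(staging, "counts.csv"))
    write_run_report(report, file.path(staging, "run_report.txt"))
    if (!dir.exists(outdir) &&
        !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
      unlink(staging, recursive = TRUE)
      stop("stage output: cannot create directory ", outdir)
    }
    # stage fully, then move: no partial matrix on failure
    for (f in list.files(staging, full.names = TRUE))
      if (!file.copy(f, file.path(outdir, basename(f)),
                     overwrite = TRUE)) {
        unlink(staging, recursive = TRUE)
        stop("stage output: cannot write into ", outdir)
      }
    unlink(staging, recursive = TRUE)
    say("wrote matrix and report to ", outdir)
  }
  list(matrix = mat, report = report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_run_report(x), sep = "\n")
  invisible(x)
}

format_run_report <- function(x) {
  p <- x$params
  c("antibody-tag counting run report",
    "--------------------------------",
    paste0("read pairs total:            ", x$reads_total),
    paste0("skipped (too short):         ", x$reads_skipped_short),
    paste0("cell barcode  unique/none/ambiguous: ", x$cell_unique, "/",
           x$cell_none, "/", x$cell_ambiguous,
           "  (distinct ambiguous barcodes: ",
           x$cell_ambiguous_distinct, ")"),
    paste0("oligo tag     unique/none/ambiguous: ", x$oligo_unique, "/",
           x$oligo_none, "/", x$oligo_ambiguous,
           "  (distinct ambiguous tags: ",
           x$oligo_ambiguous_distinct, ")"),
    paste0("assigned (unique in both):   ", x$reads_assigned),
    paste0("UMI duplicates removed:      ", x$umi_duplicates_removed),
    paste0("reads in matrix:             ", x$reads_in_matrix),
    "",
    paste0("layout: barcode [", p$layout$barcode_start, ",",
           p$layout$barcode_start + p$layout$barcode_len, ") umi [",
           p$layout$umi_start, ",",
           p$layout$umi_start + p$layout$umi_len, ") tag [",
           p$layout$tag_start, ",",
           p$layout$tag_start + p$layout$tag_len, ")"),
    paste0("match: cell_max_mismatch=", p$match$cell_max_mismatch,
           " oligo_min_ratio=", p$match$oligo_min_ratio,
           " chunk_size=", p$match$chunk_size,
           " threads=", p$match$threads),
    paste0("dedup: mode=", p$dedup$mode,
           " umi_max_mismatch=", p$dedup$umi_max_mismatch,
           " key_scope=", p$dedup$key_scope))
}

#' Write the run report as plain text
#'
#' @param report A `run_report` from [run_count()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_report <- function(report, path) {
  writeLines(format_run_report(report), path)
  invisible(path)
}
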