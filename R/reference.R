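is_dna <- function(x) grepl("^[ACGTN]+$", x)

#' Oligo reference panel
#'
#' The marker-name-to-tag-sequence table that oligo reads are matched
#' against. Names and sequences must be unique and all sequences the same
#' length (the tag width).
#'
#' @param names Character vector of marker names (e.g. `"CD4"`).
#' @param sequences Character vector of tag sequences over `{A,C,G,T}`.
#' @return An `oligo_reference`: data.frame with columns `name`, `sequence`.
#' @seealso [load_oligo_reference()] to read one from a delimited file.
#' @export
oligo_reference <- function(names, sequences) {
  names <- as.character(names)
  sequences <- toupper(as.character(sequences))
  if (length(names) == 0L) stop("oligo reference must be non-empty")
  if (length(names) != length(sequences))
    stop("names and sequences differ in length")
  dup <- unique(names[duplicated(names)])
  if (length(dup))
    stop("duplicate marker names in oligo reference: ",
         paste(dup, collapse = ", "))
  dup <- unique(sequences[duplicated(sequences)])
  if (length(dup))
    stop("duplicate sequences in oligo reference: ",
         paste(dup, collapse = ", "))
  if (length(unique(nchar(sequences))) != 1L)
    stop("oligo reference sequences have ragged lengths: ",
         paste(sort(unique(nchar(sequences))), collapse = ", "))
  bad <- !is_dna(sequences)
  if (any(bad))
    stop("non-ACGT characters in oligo sequences: ",
         paste(names[bad], collapse = ", "))
  structure(data.frame(name = names, sequence = sequences,
                       stringsAsFactors = FALSE),
            class = c("oligo_reference", "data.frame"))
}

#' Read an oligo reference panel from a delimited file
#'
#' Expects two columns (marker name, tag sequence), comma- or tab-separated,
#' with an optional header line. A first line whose second field is not a
#' DNA sequence is treated as a header and skipped.
#'
#' @param path Path to the file (plain or gzipped).
#' @return An [oligo_reference()].
#' @export
load_oligo_reference <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty oligo reference file: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("oligo reference must have two columns (name, sequence): ", path)
  name <- trimws(vapply(fields, `[[`, "", 1L))
  seq <- toupper(trimws(vapply(fields, `[[`, "", 2L)))
  if (!is_dna(seq[[1]]) && length(seq) > 1L) { # header line
    name <- name[-1]
    seq <- seq[-1]
  }
  oligo_reference(name, seq)
}

#' Cell-barcode whitelist
#'
#' The set of valid cell barcodes that cell-ID reads are matched against,
#' either from the chemistry manufacturer or from the cells called by a
#' companion ATAC/RNA pipeline. Barcodes must be unique and equal-length.
#'
#' @param barcodes Character vector of barcodes over `{A,C,G,T}`.
#' @return A `cell_whitelist`: character vector with class attribute.
#' @seealso [load_whitelist()]
#' @export
cell_whitelist <- function(barcodes) {
  barcodes <- toupper(as.character(barcodes))
  if (length(barcodes) == 0L) stop("whitelist must be non-empty")
  dup <- unique(barcodes[duplicated(barcodes)])
  if (length(dup))
    stop("duplicate barcodes in whitelist: ",
         paste(head(dup, 5L), collapse = ", "))
  if (length(unique(nchar(barcodes))) != 1L)
    stop("whitelist barcodes have mixed lengths: ",
         paste(sort(unique(nchar(barcodes))), collapse = ", "))
  bad <- !is_dna(barcodes)
  if (any(bad))
    stop("non-ACGT characters in whitelist barcodes (first: ",
         barcodes[bad][1L], ")")
  structure(barcodes, class = "cell_whitelist")
}

#' Read a cell-barcode whitelist from a text file
#'
#' One barcode per line, optionally gzipped. Suffixes after a dash (the
#' `-1` gem-group suffix emitted by droplet pipelines) are stripped before
#' validation.
#'
#' @param path Path to the file.
#' @return A [cell_whitelist()].
#' @export
load_whitelist <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty whitelist file: ", path)
  cell_whitelist(sub("-.*$", "", lines))
}
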