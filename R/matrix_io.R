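#' Feature-by-barcode count matrix
#'
#' Wraps a sparse integer matrix with rows in oligo-reference order and
#' columns in whitelist order. Dimensions are always the full
#' `|reference| x |whitelist|`, independent of which entries are nonzero.
#'
#' @param counts Matrix-like of non-negative integers, or NULL for all-zero.
#' @param features Marker names in reference order (row names).
#' @param barcodes Whitelist barcodes in whitelist order (column names).
#' @return A `count_matrix`: `dgCMatrix` with dimnames set.
#' @export
count_matrix <- function(counts = NULL, features, barcodes) {
  nf <- length(features)
  nb <- length(barcodes)
  if (is.null(counts))
    counts <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                   x = numeric(), dims = c(nf, nb))
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (!all(dim(m) == c(nf, nb)))
    stop("counts dimensions ", nrow(m), "x", ncol(m),
         " do not match ", nf, " features x ", nb, " barcodes")
  if (any(m@x < 0) || any(m@x != round(m@x)))
    stop("counts must be non-negative integers")
  dimnames(m) <- list(as.character(features), as.character(barcodes))
  Matrix::drop0(m)
}

#' Write a count matrix as a CellRanger-style sparse triplet
#'
#' Writes three gzipped files into `outdir`: `matrix.mtx.gz` (MatrixMarket
#' `coordinate integer general`, 1-based indices, features as rows),
#' `barcodes.tsv.gz` (one barcode per line, whitelist order) and
#' `features.tsv.gz` (id, name and the literal feature type
#' `"Antibody Capture"`). [read_mtx_triplet()] reproduces the matrix
#' exactly.
#'
#' @param matrix A [count_matrix()] (any dgCMatrix with dimnames works).
#' @param outdir Output directory, created if absent.
#' @return Invisibly, the three file paths.
#' @export
write_mtx_triplet <- function(matrix, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  m <- Matrix::drop0(methods::as(matrix, "CsparseMatrix"))
  trip <- Matrix::summary(m)
  mtx_path <- file.path(outdir, "matrix.mtx.gz")
  con <- gzfile(mtx_path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "%"),
             con)
  writeLines(paste(nrow(m), ncol(m), nrow(trip)), con)
  if (nrow(trip) > 0L) {
    ord <- order(trip$j, trip$i) # column-major, CellRanger convention
    writeLines(paste(trip$i[ord], trip$j[ord],
                     as.integer(trip$x[ord])), con)
  }
  bc_path <- file.path(outdir, "barcodes.tsv.gz")
  con2 <- gzfile(bc_path, "wt")
  writeLines(colnames(m), con2)
  close(con2)
  ft_path <- file.path(outdir, "features.tsv.gz")
  con3 <- gzfile(ft_path, "wt")
  writeLines(paste(rownames(m), rownames(m), "Antibody Capture",
                   sep = "\t"), con3)
  close(con3)
  invisible(c(matrix = mtx_path, barcodes = bc_path, features = ft_path))
}

#' Read back a sparse-triplet count matrix
#'
#' @param outdir Directory written by [write_mtx_triplet()].
#' @return A [count_matrix()].
#' @export
read_mtx_triplet <- function(outdir) {
  m <- Matrix::readMM(file.path(outdir, "matrix.mtx.gz"))
  barcodes <- readLines(file.path(outdir, "barcodes.tsv.gz"))
  feat <- read.delim(file.path(outdir, "features.tsv.gz"),
                     header = FALSE, stringsAsFactors = FALSE)
  count_matrix(m, features = feat[[2]], barcodes = barcodes)
}

#' Write a count matrix as a dense CSV
#'
#' Features as rows (marker names in the first column, headed `marker`),
#' whitelist barcodes as column headers.
#'
#' @param matrix A [count_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dense_csv <- function(matrix, path) {
  dense <- as.matrix(matrix)
  con <- tryCatch(file(path, "wt"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("marker", colnames(dense)), collapse = ","), con)
  body <- apply(dense, 1L, function(r)
    paste(as.integer(r), collapse = ","))
  writeLines(paste(rownames(dense), body, sep = ","), con)
  invisible(path)
}

#' Read back a dense CSV count matrix
#'
#' @param path File written by [write_dense_csv()].
#' @return A [count_matrix()].
#' @export
read_dense_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  count_matrix(m, features = df[[1]], barcodes = colnames(df)[-1])
}
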