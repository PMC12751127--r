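test_that("read layout validates windows and rejects overlap", {
  l <- read_layout()
  expect_equal(l$barcode_len, 16L)
  expect_equal(l$umi_start, 16L)
  expect_equal(l$umi_len, 12L)
  expect_equal(l$tag_len, 16L)
  expect_error(read_layout(barcode_start = -1), "must be >= 0")
  expect_error(read_layout(umi_start = 10), "overlap")
  expect_error(read_layout(umi_len = 0), ">= 1")
})

test_that("paired FASTQ reading extracts windows, concatenates lanes and skips short reads", {
  d <- withr::local_tempdir()
  layout <- read_layout(barcode_len = 4, umi_start = 4, umi_len = 3,
                        tag_len = 4)
  # lane 1: 2 good pairs; lane 2: 1 good + 1 short cell read
  write_tiny_fastq(c("r1", "r2"), c("ACGTAAACC", "TTTTCCCGG"),
                   file.path(d, "c1.fastq"))
  write_tiny_fastq(c("r1", "r2"), c("AAAA", "CCCC"),
                   file.path(d, "o1.fastq"))
  write_tiny_fastq(c("r3", "r4"), c("GGGGTTTAA", "ACGT"),
                   file.path(d, "c2.fastq.gz"))
  write_tiny_fastq(c("r3", "r4"), c("GGGG", "TTTT"),
                   file.path(d, "o2.fastq.gz"))
  fq <- read_paired_fastq(file.path(d, c("c1.fastq", "c2.fastq.gz")),
                          file.path(d, c("o1.fastq", "o2.fastq.gz")),
                          layout)
  expect_equal(fq$reads_total, 4L)
  expect_equal(fq$reads_skipped_short, 1L)
  expect_equal(fq$reads$read_id, c("r1", "r2", "r3"))
  expect_equal(fq$reads$cell_seq, c("ACGT", "TTTT", "GGGG"))
  expect_equal(fq$reads$umi_seq, c("AAA", "CCC", "TTT"))
  expect_equal(fq$reads$tag_seq, c("AAAA", "CCCC", "GGGG"))
})

test_that("paired FASTQ reading fails hard on mismatched lanes and empty input", {
  d <- withr::local_tempdir()
  write_tiny_fastq("r1", "ACGTACGTACGT", file.path(d, "c.fastq"))
  write_tiny_fastq(c("r1", "r2"), c("AAAA", "CCCC"),
                   file.path(d, "o.fastq"))
  expect_error(
    read_paired_fastq(file.path(d, "c.fastq"), file.path(d, "o.fastq"),
                      read_layout(barcode_len = 4, umi_start = 4,
                                  umi_len = 4, tag_len = 4)),
    "lane 1.*record counts differ")
  expect_error(
    read_paired_fastq(file.path(d, c("c.fastq", "x.fastq")),
                      file.path(d, "o.fastq")),
    "pair up lane by lane")
  writeLines(character(), file.path(d, "empty.fastq"))
  expect_error(
    read_paired_fastq(file.path(d, "empty.fastq"),
                      file.path(d, "empty.fastq")),
    "no records")
})

test_that("oligo reference loader enforces uniqueness, widths and alphabet", {
  d <- withr::local_tempdir()
  f <- file.path(d, "panel.csv")
  writeLines(c("name,sequence",
               paste0("CD4,", strrep("A", 16)),
               paste0("CD8,", strrep("C", 16))), f)
  ref <- load_oligo_reference(f)
  expect_s3_class(ref, "oligo_reference")
  expect_equal(ref$name, c("CD4", "CD8"))
  expect_equal(nchar(ref$sequence), c(16L, 16L))

  writeLines(c(paste0("CD4,", strrep("A", 16)),
               paste0("CD4,", strrep("C", 16))), f)
  expect_error(load_oligo_reference(f), "duplicate marker names.*CD4")
  writeLines(c(paste0("CD4,", strrep("A", 16)),
               paste0("CD8,", strrep("C", 15))), f)
  expect_error(load_oligo_reference(f), "ragged")
  writeLines(c(paste0("CD4,", strrep("A", 16)),
               paste0("CD8,", paste0(strrep("C", 15), "X"))), f)
  expect_error(load_oligo_reference(f), "non-ACGT")
  expect_error(oligo_reference(c("a", "b"),
                               c(strrep("A", 8), strrep("A", 8))),
               "duplicate sequences")
})

test_that("whitelist loader strips dash suffixes and validates", {
  d <- withr::local_tempdir()
  f <- file.path(d, "wl.txt")
  writeLines(c(paste0(strrep("A", 16), "-1"),
               paste0(strrep("C", 16), "-1")), f)
  wl <- load_whitelist(f)
  expect_length(wl, 2L)
  expect_equal(as.character(unclass(wl)), c(strrep("A", 16), strrep("C", 16)))
  writeLines(c(paste0(strrep("A", 16), "-1"),
               paste0(strrep("A", 16), "-2")), f)
  expect_error(load_whitelist(f), "duplicate")
  writeLines(c(strrep("A", 16), strrep("C", 15)), f)
  expect_error(load_whitelist(f), "mixed lengths")
  writeLines(character(), f)
  expect_error(load_whitelist(f), "empty")
})

test_that("MTX triplet matches the format definition and round-trips", {
  d <- withr::local_tempdir()
  m <- count_matrix(matrix(c(0, 0, 5, 0), nrow = 2),
                    features = c("CD4", "CD8"),
                    barcodes = c(strrep("A", 4), strrep("C", 4)))
  write_mtx_triplet(m, d)
  lines <- readLines(gzfile(file.path(d, "matrix.mtx.gz")))
  expect_equal(lines[[1]],
               "%%MatrixMarket matrix coordinate integer general")
  expect_equal(lines[[3]], "2 2 1")
  expect_equal(lines[[4]], "1 2 5")
  feat <- readLines(gzfile(file.path(d, "features.tsv.gz")))
  expect_true(all(grepl("\tAntibody Capture$", feat)))
  expect_equal(readLines(gzfile(file.path(d, "barcodes.tsv.gz"))),
               c("AAAA", "CCCC"))
  back <- read_mtx_triplet(d)
  expect_equal(as.matrix(back), as.matrix(m))

  zero <- count_matrix(NULL, features = c("CD4", "CD8", "CD19"),
                       barcodes = c("AAAA", "CCCC"))
  write_mtx_triplet(zero, d)
  lines <- readLines(gzfile(file.path(d, "matrix.mtx.gz")))
  expect_equal(lines[[3]], "3 2 0")
  expect_length(lines, 3L)
  expect_equal(dim(read_mtx_triplet(d)), c(3L, 2L))
})

test_that("MTX round-trip is the identity on random sparse matrices", {
  set.seed(42)
  d <- withr::local_tempdir()
  for (i in 1:5) {
    nf <- sample(1:8, 1)
    nb <- sample(1:10, 1)
    vals <- matrix(rbinom(nf * nb, 10, 0.2), nf, nb)
    m <- count_matrix(vals, features = sprintf("F%02d", seq_len(nf)),
                      barcodes = random_seqs(nb, 6))
    out <- file.path(d, paste0("m", i))
    write_mtx_triplet(m, out)
    expect_equal(as.matrix(read_mtx_triplet(out)), as.matrix(m))
  }
})

test_that("dense CSV keeps full dimensions and round-trips", {
  d <- withr::local_tempdir()
  p <- file.path(d, "counts.csv")
  one <- count_matrix(matrix(7), features = "CD4", barcodes = "ACGT")
  write_dense_csv(one, p)
  expect_equal(readLines(p), c("marker,ACGT", "CD4,7"))
  expect_equal(as.matrix(read_dense_csv(p)), as.matrix(one))

  zero <- count_matrix(NULL, features = c("CD4", "CD8"),
                       barcodes = c("AAAA", "CCCC", "GGGG"))
  write_dense_csv(zero, p)
  back <- read_dense_csv(p)
  expect_equal(dim(back), c(2L, 3L))
  expect_true(all(as.matrix(back) == 0))
})

test_that("count matrices reject negatives and dimension mismatches", {
  expect_error(count_matrix(matrix(-1), "F", "AAAA"), "non-negative")
  expect_error(count_matrix(matrix(0, 2, 2), c("a", "b"), "AAAA"),
               "do not match")
})
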