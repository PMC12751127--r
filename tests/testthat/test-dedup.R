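test_that("exact dedup keeps first occurrences per key and respects key scope", {
  reads <- assigned_reads(c(1, 1, 1), c(1, 1, 1),
                          c("AAAA", "AAAA", "CCCC"))
  res <- dedup_exact(reads)
  expect_equal(nrow(res$survivors), 2L)
  expect_equal(res$report$n_removed, 1L)
  expect_equal(res$survivors$umi_seq, c("AAAA", "CCCC"))

  distinct <- assigned_reads(1:4, c(1, 1, 2, 2),
                             c("AAAA", "CCCC", "GGGG", "TTTT"))
  res <- dedup_exact(distinct)
  expect_equal(res$survivors, distinct)
  expect_equal(res$report$n_removed, 0L)

  # same cell+UMI, different oligo: collapses under cell_umi only
  two <- assigned_reads(c(1, 1), c(1, 2), c("AAAA", "AAAA"))
  expect_equal(nrow(dedup_exact(two, dedup_params())$survivors), 1L)
  expect_equal(nrow(dedup_exact(
    two, dedup_params(key_scope = "cell_oligo_umi"))$survivors), 2L)
})

test_that("fuzzy dedup merges 1-mismatch UMIs and degenerates to exact when nothing connects", {
  pair <- assigned_reads(c(1, 1), c(1, 1), c("AAAA", "AAAT"))
  res <- dedup_fuzzy(pair, dedup_params(mode = "fuzzy"))
  expect_equal(nrow(res$survivors), 1L)
  expect_equal(res$report$n_removed, 1L)

  far <- assigned_reads(c(1, 1, 2), c(1, 1, 1),
                        c("AAAA", "TTTT", "AAAT"))
  fz <- dedup_fuzzy(far, dedup_params(mode = "fuzzy"))
  ex <- dedup_exact(far)
  expect_equal(fz$survivors, ex$survivors)

  # same UMIs in different cells never merge
  cells <- assigned_reads(c(1, 2), c(1, 1), c("AAAA", "AAAT"))
  expect_equal(nrow(dedup_fuzzy(cells,
                                dedup_params(mode = "fuzzy"))$survivors),
               2L)
})

test_that("fuzzy components keep the most frequent representative, ties lexicographic", {
  # chain GTCA(x3) - GTCC(x1) - GTCG? use adjacent-1 chain u1-u2-u3
  u1 <- "AAAA"; u2 <- "AAAT"; u3 <- "AATT"
  reads <- assigned_reads(rep(1, 5), rep(1, 5),
                          c(u1, u1, u1, u2, u3))
  res <- dedup_fuzzy(reads, dedup_params(mode = "fuzzy"))
  expect_equal(nrow(res$survivors), 1L)
  expect_equal(res$survivors$umi_seq, u1)
  expect_equal(res$survivors, reads[1, ], ignore_attr = TRUE)

  # tie on frequency: lexicographically smaller UMI survives
  tie <- assigned_reads(c(1, 1), c(1, 1), c("CCCC", "CCCA"))
  res <- dedup_fuzzy(tie, dedup_params(mode = "fuzzy"))
  expect_equal(res$survivors$umi_seq, "CCCA")
})

test_that("dedup is idempotent and conserves read counts in both modes", {
  set.seed(31)
  for (mode in c("exact", "fuzzy")) {
    params <- dedup_params(mode = mode)
    for (i in 1:5) {
      n <- sample(5:60, 1)
      reads <- assigned_reads(sample(1:4, n, TRUE), sample(1:3, n, TRUE),
                              random_seqs(n, 5))
      res <- dedup_reads(reads, params)
      expect_equal(res$report$n_input,
                   res$report$n_survivors + res$report$n_removed)
      again <- dedup_reads(res$survivors, params)
      expect_equal(again$survivors, res$survivors, ignore_attr = TRUE)
      expect_equal(again$report$n_removed, 0L)
      # fuzzy never keeps more than exact
      expect_lte(nrow(dedup_fuzzy(reads,
                                  dedup_params(mode = "fuzzy"))$survivors),
                 nrow(dedup_exact(reads)$survivors))
    }
  }
})

test_that("exact dedup surviving key-set is permutation-invariant", {
  set.seed(32)
  reads <- assigned_reads(sample(1:3, 30, TRUE), sample(1:2, 30, TRUE),
                          random_seqs(30, 4))
  keys <- function(df) sort(paste(df$cell_index, df$umi_seq))
  base <- dedup_exact(reads)$survivors
  perm <- reads[sample(nrow(reads)), ]
  shuffled <- dedup_exact(perm)$survivors
  expect_equal(keys(shuffled), keys(base))
})

test_that("dedup report histogram masses sum to the number of distinct keys", {
  set.seed(33)
  reads <- assigned_reads(sample(1:3, 50, TRUE), 1,
                          sample(c("AAAA", "CCCC", "GGGG"), 50, TRUE))
  rep_ <- dedup_exact(reads)$report
  expect_equal(sum(rep_$dup_fraction_hist), rep_$n_keys)
  expect_equal(length(rep_$dup_fraction), rep_$n_keys)
})

test_that("mode comparison reports the injected normalized differences", {
  # only exact duplicates: all differences zero
  exact_only <- assigned_reads(c(1, 1, 1), c(1, 1, 1),
                               c("AAAA", "AAAA", "GGGG"))
  cmp <- compare_dedup_modes(exact_only)
  expect_true(all(cmp$per_umi$normalized_diff == 0))
  expect_equal(cmp$frac_zero_change, 1)

  # one 1-bp-error duplicate pair of total count 2 -> one UMI at 0.5
  twin <- assigned_reads(c(1, 1), c(1, 1), c("AAAA", "AAAT"))
  cmp <- compare_dedup_modes(twin)
  expect_equal(nrow(cmp$per_umi), 1L)
  expect_equal(cmp$per_umi$total_count, 2L)
  expect_equal(cmp$per_umi$exact_dups, 0L)
  expect_equal(cmp$per_umi$fuzzy_dups, 1L)
  expect_equal(cmp$per_umi$normalized_diff, 0.5)
  expect_equal(cmp$frac_zero_change, 0)

  # empty input: empty report, no division by zero
  empty <- assigned_reads(integer(), integer(), character())
  cmp <- compare_dedup_modes(empty)
  expect_equal(nrow(cmp$per_umi), 0L)
  expect_true(is.na(cmp$frac_zero_change))
})

test_that("the comparison table writes as CSV", {
  d <- withr::local_tempdir()
  twin <- assigned_reads(c(1, 1), c(1, 1), c("AAAA", "AAAT"))
  p <- write_dedup_comparison(compare_dedup_modes(twin),
                              file.path(d, "cmp.csv"))
  got <- read.csv(p)
  expect_equal(got$normalized_diff, 0.5)
})
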