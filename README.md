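# adtcount

Antibody-derived tag counting for ASAP-seq and CITE-seq experiments.

Single-cell surface-protein assays sequence short antibody-conjugated
oligos alongside chromatin (ASAP-seq) or RNA (CITE-seq) libraries. Each
fragment yields a read pair: one read with the **cell barcode** and
**UMI**, the other with the **tag** identifying the antibody. `adtcount`
turns those paired FASTQ files into a deduplicated feature-by-barcode
count matrix in the CellRanger sparse-triplet layout
(`matrix.mtx.gz` + `barcodes.tsv.gz` + `features.tsv.gz`, feature type
`Antibody Capture`), ready for Seurat/Signac-style downstream analysis.

## Method

For each read pair, with whitelist *W* (valid cell barcodes) and oligo
panel *O* (marker → tag sequence):

1. **Cell assignment.** The extracted barcode *b* is compared to every
   *w ∈ W* by Hamming distance `d_H`; entries with
   `d_H(b, w) ≤ 1` (default) are hits. `N` never matches any base.
2. **Tag assignment.** The extracted tag *t* is compared to every
   *o ∈ O* by normalized edit-distance similarity
   `s(t, o) = 1 − d_Lev(t, o) / |o|`; entries with `s ≥ 0.93` (default,
   i.e. one mismatch on a 16-bp tag: `1 − 1/16 = 0.9375`) are hits.
3. **Ambiguity filter.** A read is kept only if it has *exactly one* hit
   on each side; reads hitting multiple cells or multiple oligos are
   dropped and tallied.
4. **UMI dedup.** Reads sharing a `(cell, UMI)` key collapse to one
   molecule (exact mode, default), or 1-mismatch UMIs are merged by
   connected components (fuzzy mode). `compare_dedup_modes()` reports the
   per-UMI normalized difference between the two.
5. **Matrix.** Each surviving molecule increments one cell of the
   `|O| × |W|` matrix; dimensions always span the full panel and
   whitelist.

Matching runs chunked (100,000 sequences per chunk by default) through a
compiled core; results are bit-identical for any chunk size or thread
count. A seeded simulator (`sim_params()`, `simulate_run()`) generates
paired FASTQ data with a known ground-truth matrix for validation.

## Worked example

Simulate a 50-cell × 8-marker experiment with barcode errors and PCR
duplicates, then count it:

```r
library(adtcount)
p <- sim_params(n_cells = 50, n_oligos = 8, mean_reads = 4,
                sub_rate_barcode = 0.01, max_subs_per_window = 1,
                dup_rate = 0.2, seed = 42)
sim <- simulate_run(p, "demo_sim")
res <- run_count("demo_sim/cellid_R1.fastq.gz",
                 "demo_sim/oligo_R2.fastq.gz",
                 "demo_sim/oligo_reference.csv",
                 "demo_sim/whitelist.txt",
                 outdir = "demo_out")
res$report
```

```
antibody-tag counting run report
--------------------------------
read pairs total:            1953
skipped (too short):         0
cell barcode  unique/none/ambiguous: 1953/0/0  (distinct ambiguous barcodes: 0)
oligo tag     unique/none/ambiguous: 1953/0/0  (distinct ambiguous tags: 0)
assigned (unique in both):   1953
UMI duplicates removed:      315
reads in matrix:             1638
```

All 1,953 read pairs match a single whitelist barcode and a single panel
oligo (the injected single-base barcode errors are absorbed by the
1-mismatch cutoff), 315 PCR duplicates collapse, and the 1,638 surviving
molecules exactly reproduce the simulation's ground-truth matrix:

```r
res$matrix[1:4, 1:3]
#>        AAAACTCCATGTGTAA CTCCGGAAGTAGAATC TTGCACTCGGCCTTTC
#> TAG001                4                7                1
#> TAG002                3                5                1
#> TAG003                4                4                5
#> TAG004                8               10                4
identical(as.matrix(res$matrix), as.matrix(sim$truth))
#> [1] TRUE
```

`demo_out/` now holds `matrix.mtx.gz`, `barcodes.tsv.gz`,
`features.tsv.gz` and `run_report.txt`. A command-line front end with the
same options lives at `inst/cli/adtcount.R`
(`Rscript adtcount.R count --help`, `... simulate --help`).

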