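---
title: "Counting antibody-derived tags: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting antibody-derived tags: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtcount)
```

## The problem

ASAP-seq and CITE-seq experiments measure cell-surface proteins by
sequencing short oligonucleotides conjugated to antibodies. Each sequenced
fragment yields a read pair: one read carries the *cell barcode* (which
droplet the molecule came from) and a *UMI* (which original molecule it
was), the other carries the *tag* identifying the antibody. Turning these
FASTQ files into a feature-by-barcode count matrix requires three
decisions per read — which cell, which marker, and whether the molecule
has already been counted — each made in the presence of sequencing error.

`adtcount` makes those decisions with tolerant string matching against two
user-supplied references (a cell-barcode whitelist and an oligo panel),
drops reads whose assignment is ambiguous, collapses UMI duplicates, and
writes the result in the CellRanger sparse-triplet layout so standard
single-cell toolkits can load it directly.

## Matching model

Two metrics, one per reference, reflect the different error structure of
the two windows:

* **Cell barcodes — Hamming distance.** Barcodes are fixed-width windows;
  substitution is the dominant error mode. A barcode is accepted within
  `cell_max_mismatch` mismatches of a whitelist entry (default **1**).
  A window whose length differs from the whitelist width can never match.
* **Tags — normalized edit-distance ratio.** Tag reads can carry indels
  as well as substitutions, so similarity is
  `1 − levenshtein(query, ref) / nchar(ref)`, floored at 0. The default
  cutoff **0.93** corresponds to one mismatch on a 16-bp tag
  (`1 − 1/16 = 0.9375` passes; two mismatches give `0.875` and fail).
  Tolerating more than one mismatch is known to recover only marginal
  additional signal while inviting misassignment, which is why both
  defaults sit at the one-error level.

`N` bases are treated as unknown: an `N` never matches any base,
including another `N`, under either metric.

**Ambiguity.** A read whose window meets the cutoff for two or more
reference entries is *ambiguous* and is dropped, even if one hit is
strictly closer. A best-hit rescue would make results depend on tie-break
order and on reference listing order; dropping is conservative,
deterministic, and the tallies (reads and distinct offending sequences)
are reported so panel-design problems are visible.

**Chunking and threads.** Batches are processed in chunks
(`chunk_size`, default 100,000 sequences) to bound the memory of the
all-pairs distance computation, optionally across forked workers. Because
each read is scored independently, results are bit-identical for every
chunk size and thread count; the test suite asserts this directly.
Matching is brute force by design — correctness is defined by an
all-pairs scan, and panel sizes (tens to hundreds of oligos, whitelists
up to ~10^5) keep the compiled scan fast without k-mer indexing.

## UMI deduplication

The dedup key defaults to `(cell, UMI)`; a `(cell, oligo, UMI)` scope is
available (`key_scope = "cell_oligo_umi"`) and is the convention of most
feature-barcode pipelines — with well-separated UMIs the two agree, and
the default follows the narrower published definition.

* **Exact mode (default).** Reads sharing an identical key collapse to
  the first occurrence in input order. On real tag data the large
  majority of UMI keys show no difference between exact and 1-mismatch
  duplicate identification, which is why exact is the default.
* **Fuzzy mode.** Within each cell (and oligo, if scoped), distinct UMIs
  are joined by an edge when their Hamming distance is at most
  `umi_max_mismatch` (default 1); each connected component keeps exactly
  one representative — the most frequent UMI, ties broken
  lexicographically — and the first input occurrence of that UMI
  survives. Connected components were chosen over directional/abundance
  network methods because they are deterministic, order-independent and
  parameter-free beyond the radius; UMIs are fixed-width windows, so
  Hamming is the natural metric (at radius 1 it coincides with edit
  distance on equal-length strings).

`compare_dedup_modes()` quantifies the difference per UMI component: the
extra duplicates fuzzy clustering finds, divided by the component's total
read count (so a 1-bp twin pair of total count 2 scores 0.5), plus the
fraction of components with no change at all.

## Pipeline contract

`run_count()` computes the cell match and the tag match independently,
keeps reads unique in *both*, deduplicates, and increments one matrix
cell per surviving molecule. The matrix always has the maximal dimensions
`|panel| × |whitelist|`, including all-zero rows and columns, so outputs
from different runs align structurally. The run report carries a
conservation ledger — every read is skipped-short, filtered (none or
ambiguous on either side), a removed duplicate, or counted — and the
matrix grand total always equals `reads_in_matrix`. Output files are
staged in a temporary directory and moved only when complete, so a failed
run leaves no partial matrix. An empty matrix is a valid result, not an
error.

Reads too short for any configured window are skipped and tallied, never
padded. Base qualities are ignored. Reads are used exactly as sequenced;
no reverse-complementing is applied to reads, whitelist or panel.

## The simulator

`sim_params()` / `simulate_run()` generate paired FASTQ data with known
ground truth so every stage is testable without external downloads. The
defaults — 200 cells × 20 oligos at a mean of 5 molecules per pair,
16/12/16-bp barcode/UMI/tag geometry, no noise — describe a small but
complete experiment; noise processes are switched on individually:

* per-base substitution rates for barcode, UMI and tag, with an optional
  per-window cap (`max_subs_per_window = 1` reproduces the
  at-most-one-error regime the default cutoffs absorb);
* PCR duplicates (identical UMI) and fuzzy duplicates (1-base UMI error);
* ambient reads with off-whitelist barcodes;
* an ambiguous-bait mode that plants an oligo pair at Hamming distance 2
  and emits reads equidistant between them;
* a tag indel switch for stressing the ratio metric (off by default,
  matching the substitution-centric cutoff design).

Three constructions make the ground truth an *exact* oracle rather than
an approximate one: whitelist barcodes and panel oligos are sampled at
pairwise Hamming distance ≥ 3 (uniquely decodable under one error);
molecule UMIs within a cell are drawn at pairwise distance ≥ 3 (neither
exact nor 1-mismatch dedup can merge two different molecules); fuzzy-twin
UMIs are placed so they touch only their source molecule, and ambient
barcodes sit at distance ≥ 2 from the whitelist so they can never be
rescued. These choices are what the simulator deliberately does *not*
share with real data — real barcode sets are not distance-separated, real
UMIs collide, real ambient material can sit one error from a valid
barcode, and quality scores, fragment-length variation and lane effects
are absent. Passing tests therefore demonstrate algorithmic correctness
under decodable conditions, not end-to-end accuracy on any particular
dataset.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; MTX indices are 1-based
  as the format requires; MTX entries are written column-major.
* Whitelist loading strips `-1`-style gem-group suffixes before
  validating uniqueness.
* Fuzzy-component ties break by frequency first, then lexicographic
  order, so results never depend on input order beyond which duplicate
  copy survives.
* Empty read sets, all-zero matrices and empty dedup inputs flow through
  every stage without special-casing or division by zero.
* Reference generation is rejection sampling with a sphere-packing
  feasibility bound and a stall guard, so infeasible requests fail fast
  with a clear message.

## Validation scale

The shipped tests and the acceptance script validate on simulations of
200 cells × 20 oligos at a mean of 5 reads per pair (~20,000 read pairs)
for ground-truth recovery, 1,000 random 16-mers against 8 references for
oracle equivalence, and 60–100-cell runs for dedup and determinism
checks — sizes chosen so the full suite exercises every code path in
well under a minute per property while remaining large enough that
coincidental passes are implausible.

## Known limitations

* No cell calling: the whitelist *is* the cell set. Knee-point detection
  belongs to the upstream ATAC/RNA pipeline.
* No quality-aware matching, no reverse-complement auto-detection, no
  BCL conversion, no HDF5 output.
* Matching cost grows with `|reads| × |whitelist|`; very large
  whitelists (10^6 barcodes) are workable but slow without an index,
  which is out of scope by design.
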