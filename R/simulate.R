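BASES <- c("A", "C", "G", "T")

rand_seqs <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Substitute at a single random position, always to a different base.
mutate_one <- function(seq) {
  pos <- sample.int(nchar(seq), 1L)
  old <- substr(seq, pos, pos)
  substr(seq, pos, pos) <- sample(setdiff(BASES, old), 1L)
  seq
}

mutate_n <- function(seq, n_subs) {
  if (n_subs == 0L) return(seq)
  pos <- sample.int(nchar(seq), min(n_subs, nchar(seq)))
  for (p in pos) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(BASES, old), 1L)
  }
  seq
}

#' Simulation parameters
#'
#' Defaults describe a small but fully featured experiment: 200 cells by
#' 20 antibody oligos at a mean of 5 molecules per (cell, oligo) pair,
#' standard droplet geometry (16-bp barcode, 12-bp UMI, 16-bp tag), and no
#' injected noise. Error and duplication processes are switched on
#' individually for stress tests.
#'
#' @param n_cells,n_oligos Whitelist and reference panel sizes.
#' @param barcode_len,umi_len,tag_len Sequence widths in bases.
#' @param mean_reads Mean molecules per (cell, oligo) pair (Poisson).
#' @param sub_rate_barcode,sub_rate_umi,sub_rate_tag Per-base substitution
#'   probabilities applied independently to each emitted read.
#' @param max_subs_per_window Cap on substitutions per window per read
#'   (`Inf` = uncapped); `1` reproduces the at-most-one-mismatch regime the
#'   default cutoffs are designed to absorb.
#' @param dup_rate Probability a molecule is re-emitted with an identical
#'   UMI (PCR duplicate).
#' @param fuzzy_dup_rate Probability a molecule is re-emitted with a 1-base
#'   UMI error (sequencing error on a PCR duplicate).
#' @param ambient_rate Expected ambient reads (barcodes off the whitelist,
#'   unmatchable at the default cutoff) per true molecule.
#' @param ambiguous_bait If TRUE, the oligo panel includes a pair at
#'   Hamming distance 2 and reads equidistant between them are emitted,
#'   exercising the ambiguity filter.
#' @param tag_indel_rate Probability a tag read carries a 1-base deletion
#'   (bases shift left, a random base pads the end); stresses the
#'   edit-ratio metric. Off by default: the matching cutoffs are framed
#'   around substitutions.
#' @param seed Integer seed; every simulation function is deterministic
#'   given (params, seed).
#' @return A `sim_params` object.
#' @export
sim_params <- function(n_cells = 200L, n_oligos = 20L,
                       barcode_len = 16L, umi_len = 12L, tag_len = 16L,
                       mean_reads = 5, sub_rate_barcode = 0,
                       sub_rate_umi = 0, sub_rate_tag = 0,
                       max_subs_per_window = Inf,
                       dup_rate = 0, fuzzy_dup_rate = 0,
                       ambient_rate = 0, ambiguous_bait = FALSE,
                       tag_indel_rate = 0, seed = 1L) {
  rates <- c(sub_rate_barcode, sub_rate_umi, sub_rate_tag, dup_rate,
             fuzzy_dup_rate, tag_indel_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (ambient_rate < 0) stop("ambient_rate must be >= 0")
  if (min(n_cells, n_oligos, barcode_len, umi_len, tag_len) < 1)
    stop("sizes and lengths must be >= 1")
  structure(list(n_cells = as.integer(n_cells),
                 n_oligos = as.integer(n_oligos),
                 barcode_len = as.integer(barcode_len),
                 umi_len = as.integer(umi_len),
                 tag_len = as.integer(tag_len),
                 mean_reads = mean_reads,
                 sub_rate_barcode = sub_rate_barcode,
                 sub_rate_umi = sub_rate_umi,
                 sub_rate_tag = sub_rate_tag,
                 max_subs_per_window = max_subs_per_window,
                 dup_rate = dup_rate,
                 fuzzy_dup_rate = fuzzy_dup_rate,
                 ambient_rate = ambient_rate,
                 ambiguous_bait = ambiguous_bait,
                 tag_indel_rate = tag_indel_rate,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Rejection-sample n sequences of width len with pairwise Hamming
# distance >= min_dist. Errors out when the request is clearly infeasible
# (sphere-packing bound) or sampling stalls.
sample_separated <- function(n, len, min_dist = 3L) {
  log_space <- len * log(4)
  vol <- 1 + 3 * len + if (min_dist > 2) 9 * len * (len - 1) / 2 else 0
  if (log(n) + log(vol) > log_space)
    stop("cannot place ", n, " sequences of length ", len,
         " at pairwise distance >= ", min_dist)
  out <- character(n)
  got <- 0L
  attempts <- 0L
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n)
      stop("sequence sampling stalled: ", n, " sequences of length ",
           len, " at pairwise distance >= ", min_dist, " is infeasible")
    cand <- rand_seqs(1L, len)
    if (got == 0L ||
        .match_hamming_cpp(cand, out[seq_len(got)],
                           min_dist - 1L)$n_hits[[1]] == 0L) {
      got <- got + 1L
      out[got] <- cand
    }
  }
  out
}

#' Generate a random whitelist and oligo reference panel
#'
#' Barcodes and oligo sequences are sampled with pairwise Hamming distance
#' at least 3, making them uniquely decodable under the default 1-mismatch
#' regime. With `ambiguous_bait` the last two oligos sit at distance
#' exactly 2, so a read equidistant between them is ambiguous at the
#' default cutoffs.
#'
#' @param params A [sim_params()].
#' @param seed Seed; defaults to `params$seed`.
#' @return List with `whitelist` ([cell_whitelist()]) and `oligos`
#'   ([oligo_reference()], markers named `TAG001`, `TAG002`, ...).
#' @export
make_references <- function(params = sim_params(), seed = params$seed) {
  set.seed(seed)
  wl <- sample_separated(params$n_cells, params$barcode_len, 3L)
  og <- sample_separated(params$n_oligos, params$tag_len, 3L)
  if (params$ambiguous_bait && params$n_oligos >= 2L) {
    # rewrite the last oligo as a distance-2 neighbour of the second-last
    base <- og[params$n_oligos - 1L]
    repeat {
      twin <- mutate_n(base, 2L)
      if (hamming_distance(twin, base) == 2L && !(twin %in% og)) break
    }
    og[params$n_oligos] <- twin
  }
  list(whitelist = cell_whitelist(wl),
       oligos = oligo_reference(sprintf("TAG%03d", seq_along(og)), og))
}

# Distinct UMIs per cell at pairwise distance >= 3, so that neither exact
# nor 1-mismatch fuzzy dedup can merge two different molecules.
sample_cell_umis <- function(k, len) sample_separated(k, len, 3L)

#' Emit simulated paired reads with ground truth
#'
#' Draws molecules per (cell, oligo) pair from a Poisson with mean
#' `mean_reads`, injects PCR duplicates, 1-base-UMI fuzzy duplicates,
#' per-base substitution errors, ambient reads and (optionally)
#' oligo-ambiguous bait reads, then shuffles read order. The ground-truth
#' matrix counts distinct true molecules: duplicates collapse, ambient and
#' bait reads are excluded.
#'
#' @param params A [sim_params()].
#' @param refs References from [make_references()].
#' @param seed Seed; defaults to `params$seed + 1` so reference sampling
#'   and read emission draw independent streams.
#' @return List with `reads` (data.frame: `read_id`, `cell_read`,
#'   `oligo_read` and provenance columns), `truth` ([count_matrix()]) and
#'   `provenance` (alias of `reads` minus the raw sequences).
#' @export
emit_reads <- function(params = sim_params(), refs = make_references(params),
                       seed = params$seed + 1L) {
  set.seed(seed)
  wl <- as.character(unclass(refs$whitelist))
  og <- refs$oligos$sequence
  n_pairs <- params$n_cells * params$n_oligos
  nmol <- rpois(n_pairs, params$mean_reads)
  mol_cell <- rep(rep(seq_len(params$n_cells), params$n_oligos), nmol)
  mol_oligo <- rep(rep(seq_len(params$n_oligos),
                       each = params$n_cells), nmol)
  M <- sum(nmol)

  mol_umi <- character(M)
  for (c_idx in unique(mol_cell)) {
    rows <- which(mol_cell == c_idx)
    mol_umi[rows] <- sample_cell_umis(length(rows), params$umi_len)
  }

  truth <- count_matrix(
    Matrix::sparseMatrix(i = mol_oligo, j = mol_cell, x = rep(1, M),
                         dims = c(params$n_oligos, params$n_cells)),
    features = refs$oligos$name, barcodes = wl)

  kind <- rep("molecule", M)
  cell_idx <- mol_cell
  oligo_idx <- mol_oligo
  umi <- mol_umi

  if (M > 0 && params$dup_rate > 0) {
    dup <- which(rbinom(M, 1L, params$dup_rate) == 1L)
    kind <- c(kind, rep("pcr_duplicate", length(dup)))
    cell_idx <- c(cell_idx, mol_cell[dup])
    oligo_idx <- c(oligo_idx, mol_oligo[dup])
    umi <- c(umi, mol_umi[dup])
  }
  if (M > 0 && params$fuzzy_dup_rate > 0) {
    fz <- which(rbinom(M, 1L, params$fuzzy_dup_rate) == 1L)
    twin_by_cell <- list()
    for (i in fz) {
      cl <- as.character(mol_cell[i])
      # a safe twin touches only its source: at least 2 away from every
      # other molecule UMI and every earlier twin in the same cell
      others <- c(setdiff(mol_umi[mol_cell == mol_cell[i]], mol_umi[i]),
                  twin_by_cell[[cl]])
      tw <- NULL
      for (try in 1:25) {
        cand <- mutate_one(mol_umi[i])
        clear <- length(others) == 0L ||
          .match_hamming_cpp(cand, others, 1L)$n_hits[[1]] == 0L
        if (clear) { tw <- cand; break }
      }
      if (is.null(tw)) next # no safe twin found; skip this duplicate
      twin_by_cell[[cl]] <- c(twin_by_cell[[cl]], tw)
      kind <- c(kind, "fuzzy_duplicate")
      cell_idx <- c(cell_idx, mol_cell[i])
      oligo_idx <- c(oligo_idx, mol_oligo[i])
      umi <- c(umi, tw)
    }
  }
  ambient_bc <- character()
  if (M > 0 && params$ambient_rate > 0) {
    n_amb <- rpois(1L, params$ambient_rate * M)
    for (i in seq_len(n_amb)) {
      repeat { # off-whitelist by more than the default cutoff
        cand <- rand_seqs(1L, params$barcode_len)
        if (.match_hamming_cpp(cand, wl, 1L)$n_hits[[1]] == 0L) break
      }
      ambient_bc <- c(ambient_bc, cand)
    }
    kind <- c(kind, rep("ambient", n_amb))
    cell_idx <- c(cell_idx, rep(NA_integer_, n_amb))
    oligo_idx <- c(oligo_idx, sample.int(params$n_oligos, n_amb,
                                         replace = TRUE))
    umi <- c(umi, rand_seqs(n_amb, params$umi_len))
  }
  bait_tag <- NULL
  if (params$ambiguous_bait && params$n_oligos >= 2L && M > 0) {
    n_bait <- max(1L, rpois(1L, 0.02 * M))
    a <- og[params$n_oligos - 1L]
    b <- og[params$n_oligos]
    diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    bait_tag <- a
    substr(bait_tag, diffpos[1], diffpos[1]) <-
      substr(b, diffpos[1], diffpos[1]) # distance 1 from both a and b
    kind <- c(kind, rep("ambiguous_bait", n_bait))
    cell_idx <- c(cell_idx, sample.int(params$n_cells, n_bait,
                                       replace = TRUE))
    oligo_idx <- c(oligo_idx, rep(NA_integer_, n_bait))
    umi <- c(umi, rand_seqs(n_bait, params$umi_len))
  }

  n_reads <- length(kind)
  barcode <- ifelse(is.na(cell_idx), NA_character_, wl[cell_idx])
  if (length(ambient_bc)) barcode[kind == "ambient"] <- ambient_bc
  tag <- ifelse(is.na(oligo_idx), NA_character_, og[oligo_idx])
  if (!is.null(bait_tag)) tag[kind == "ambiguous_bait"] <- bait_tag

  inject <- function(seqs, rate, skip) {
    n_subs <- integer(length(seqs))
    if (rate > 0 && any(!skip)) {
      len <- nchar(seqs[!skip][1])
      draw <- rbinom(length(seqs), len, rate)
      draw <- pmin(draw, params$max_subs_per_window)
      draw[skip] <- 0L
      for (i in which(draw > 0L)) seqs[i] <- mutate_n(seqs[i], draw[i])
      n_subs <- as.integer(draw)
    }
    list(seqs = seqs, n_subs = n_subs)
  }
  untouched <- kind %in% c("ambient", "ambiguous_bait")
  bc <- inject(barcode, params$sub_rate_barcode, untouched)
  um <- inject(umi, params$sub_rate_umi, untouched)
  tg <- inject(tag, params$sub_rate_tag, untouched)

  tag_final <- tg$seqs
  indel <- logical(n_reads)
  if (params$tag_indel_rate > 0) {
    indel <- rbinom(n_reads, 1L, params$tag_indel_rate) == 1L & !untouched
    for (i in which(indel)) {
      p <- sample.int(nchar(tag_final[i]), 1L)
      tag_final[i] <- paste0(substr(tag_final[i], 1L, p - 1L),
                             substr(tag_final[i], p + 1L,
                                    nchar(tag_final[i])),
                             sample(BASES, 1L))
    }
  }

  ord <- sample.int(n_reads)
  reads <- data.frame(
    read_id = sprintf("sim_%07d", seq_len(n_reads)),
    cell_read = paste0(bc$seqs, um$seqs)[ord],
    oligo_read = tag_final[ord],
    kind = kind[ord],
    true_cell = cell_idx[ord],
    true_oligo = oligo_idx[ord],
    true_umi = umi[ord],
    n_sub_barcode = bc$n_subs[ord],
    n_sub_umi = um$n_subs[ord],
    n_sub_tag = tg$n_subs[ord],
    tag_indel = indel[ord],
    stringsAsFactors = FALSE)

  list(reads = reads, truth = truth,
       provenance = reads[, setdiff(names(reads),
                                    c("cell_read", "oligo_read"))])
}

write_fastq <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  if (length(ids)) {
    qual <- strrep("I", nchar(seqs))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Run a full simulation and write its files
#'
#' Generates references and reads, then writes the paired FASTQ files, the
#' oligo reference CSV, the whitelist, the ground-truth matrix (sparse
#' triplet) and the per-read provenance table into `outdir`.
#'
#' @param params A [sim_params()].
#' @param outdir Output directory, created if absent.
#' @param seed Seed; defaults to `params$seed`.
#' @return List with `paths` (named file paths), `refs`, `truth` and
#'   `provenance`, invisibly.
#' @export
simulate_run <- function(params = sim_params(), outdir,
                         seed = params$seed) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  refs <- make_references(params, seed)
  sim <- emit_reads(params, refs, seed + 1L)
  paths <- c(cellid_fastq = file.path(outdir, "cellid_R1.fastq.gz"),
             oligo_fastq = file.path(outdir, "oligo_R2.fastq.gz"),
             oligos = file.path(outdir, "oligo_reference.csv"),
             whitelist = file.path(outdir, "whitelist.txt"),
             truth = file.path(outdir, "truth"),
             provenance = file.path(outdir, "provenance.csv"))
  write_fastq(sim$reads$read_id, sim$reads$cell_read,
              paths[["cellid_fastq"]])
  write_fastq(sim$reads$read_id, sim$reads$oligo_read,
              paths[["oligo_fastq"]])
  writeLines(paste(refs$oligos$name, refs$oligos$sequence, sep = ","),
             paths[["oligos"]])
  writeLines(as.character(unclass(refs$whitelist)), paths[["whitelist"]])
  write_mtx_triplet(sim$truth, paths[["truth"]])
  write.csv(sim$provenance, paths[["provenance"]], row.names = FALSE,
            quote = FALSE)
  invisible(list(paths = paths, refs = refs, truth = sim$truth,
                 provenance = sim$provenance))
}
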