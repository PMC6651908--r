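#' Simulate paired reads from a synthetic transcriptome
#'
#' Draws fragments from transcripts with probability proportional to
#' `abundance * w(GC(fragment))`, where `w` is the configured fragment-level
#' GC-bias function (`NULL` means unbiased).  Bases are error-free; mate 1
#' is the fragment's 5' end on the transcript strand, mate 2 the reverse
#' complement of its 3' end (FR orientation).  PCR duplicates are injected
#' at the configured rate as exact coordinate copies of earlier pairs.
#' Ground-truth genome placements are emitted for every aligned mate.
#'
#' @param genome a `GenomeModel`.
#' @param truth the `TruthTable` from [simulate_genome_annotation()].
#' @param cfg the `SimConfig` (read-geometry, bias, duplicate and seed
#'   fields are used).
#' @return list of class `ReadSimulation`: `reads` (data.table: `pair_id`,
#'   `tx_id`, transcript-space `frag_start`/`frag_len`, `duplicate`,
#'   sequences `seq1`/`seq2`), `placements` (data.table: `pair_id`,
#'   `seqname`, leftmost 0-based `pos1`/`pos2`, `strand1`/`strand2`,
#'   `proper`, `n_bases`), `quality` (constant PHRED), `read_length`.
#' @export
simulate_reads <- function(genome, truth, cfg = truth$config) {
  stopifnot(inherits(truth, "TruthTable"))
  with_seed(derive_seed(cfg$seed, "reads"), .sim_reads_impl(genome, truth, cfg))
}

.sim_reads_impl <- function(genome, truth, cfg) {
  rl <- cfg$read_length
  tx <- truth$transcripts[length_nt >= rl]
  if (nrow(tx) == 0L || all(tx$length_nt < rl))
    stop("no transcript can host a fragment of the configured read length")
  tx_seq <- transcript_sequences(genome, exons = truth$exons,
                                 tx_ids = tx$tx_id)
  tx_len <- stats::setNames(tx$length_nt, tx$tx_id)
  prob <- tx$abundance / sum(tx$abundance)

  n_total <- cfg$n_pairs
  n_spike <- as.integer(round(cfg$spike_in * n_total))
  n_real <- n_total - n_spike

  # fragment proposals with rejection sampling against w(GC(fragment))
  w <- cfg$gc_bias
  draw <- function(n) {
    idx <- sample.int(nrow(tx), n, replace = TRUE, prob = prob)
    fl <- pmin(pmax(as.integer(round(stats::rnorm(n, cfg$fragment_mean,
                                                  cfg$fragment_sd))), rl),
               tx$length_nt[idx])
    fs <- as.integer(floor(stats::runif(n) * (tx$length_nt[idx] - fl + 1L)))
    data.table::data.table(tx_idx = idx, frag_start = fs, frag_len = fl)
  }
  if (is.null(w)) {
    frags <- draw(n_real)
  } else {
    got <- list(); n_got <- 0L
    # empirical weight ceiling from the bias function on a GC grid
    wmax <- max(vapply(seq(0, 1, by = 0.01), w, numeric(1)))
    while (n_got < n_real) {
      need <- max(n_real - n_got, 1000L)
      cand <- draw(ceiling(need * 1.2))
      fseq <- substring(tx_seq[tx$tx_id[cand$tx_idx]],
                        cand$frag_start + 1L,
                        cand$frag_start + cand$frag_len)
      keep <- stats::runif(nrow(cand)) <
        vapply(gc_fraction(fseq), w, numeric(1)) / wmax
      cand <- cand[keep]
      got <- c(got, list(cand)); n_got <- n_got + nrow(cand)
    }
    frags <- data.table::rbindlist(got)[seq_len(n_real)]
  }

  # PCR duplicates: each emitted pair is, with probability duplicate_rate,
  # an exact copy of a uniformly chosen earlier original pair
  dup <- stats::runif(n_real) < cfg$duplicate_rate
  dup[1L] <- FALSE
  n_orig <- sum(!dup)
  ord_orig <- which(!dup)
  src <- integer(n_real)
  src[!dup] <- ord_orig
  if (any(dup))
    src[dup] <- ord_orig[sample.int(n_orig, sum(dup), replace = TRUE)]
  frags <- frags[src]
  frags[, duplicate := dup]

  reads <- frags[, .(tx_id = tx$tx_id[tx_idx], frag_start, frag_len,
                     duplicate)]
  fseq <- substring(tx_seq[reads$tx_id], reads$frag_start + 1L,
                    reads$frag_start + reads$frag_len)
  reads[, seq1 := substring(fseq, 1L, rl)]
  reads[, seq2 := revcomp(substring(fseq, frag_len - rl + 1L, frag_len))]

  # spike-in/contaminant pairs from a decoy sequence absent from the genome
  if (n_spike > 0L) {
    decoy_len <- max(2000L, cfg$fragment_mean * 4L)
    decoy <- random_dna(decoy_len, 0.5)
    fl <- pmin(pmax(as.integer(round(stats::rnorm(n_spike, cfg$fragment_mean,
                                                  cfg$fragment_sd))), rl),
               decoy_len)
    fs <- as.integer(floor(stats::runif(n_spike) * (decoy_len - fl + 1L)))
    dseq <- substring(decoy, fs + 1L, fs + fl)
    reads <- rbind(reads, data.table::data.table(
      tx_id = NA_character_, frag_start = fs, frag_len = fl,
      duplicate = FALSE, seq1 = substring(dseq, 1L, rl),
      seq2 = revcomp(substring(dseq, fl - rl + 1L, fl))))
  }
  reads[, pair_id := sprintf("p%07d", seq_len(.N))]
  data.table::setcolorder(reads, "pair_id")

  # ground-truth genome placements (leftmost coordinate per mate)
  aligned <- reads[!is.na(tx_id)]
  m1 <- aligned[, .(pair_id, tx_id, start0 = frag_start,
                    end0 = frag_start + rl, mate = 1L)]
  m2 <- aligned[, .(pair_id, tx_id, start0 = frag_start + frag_len - rl,
                    end0 = frag_start + frag_len, mate = 2L)]
  bl <- tx_to_genome_blocks(truth$exons, rbind(m1, m2))
  pl <- bl[, .(seqname = seqname[1L], pos = min(start0),
               tx_strand = strand[1L]), by = .(pair_id, mate)]
  pl <- data.table::dcast(pl, pair_id + seqname + tx_strand ~ mate,
                          value.var = "pos")
  data.table::setnames(pl, c("1", "2"), c("pos1", "pos2"))
  pl[, `:=`(strand1 = tx_strand,
            strand2 = data.table::fifelse(tx_strand == "+", "-", "+"),
            proper = TRUE)]
  pl[, tx_strand := NULL]
  pl[, n_bases := 2L * rl]
  data.table::setorder(pl, seqname, pos1, pair_id)

  structure(list(reads = reads[], placements = pl[],
                 quality = cfg$base_quality, read_length = rl),
            class = "ReadSimulation")
}

#' Write simulated reads as a FASTQ pair
#'
#' @param sim a `ReadSimulation`.
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @export
write_fastq <- function(sim, prefix) {
  qchar <- rawToChar(as.raw(sim$quality + 33L))
  for (m in 1:2) {
    seqs <- if (m == 1L) sim$reads$seq1 else sim$reads$seq2
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- paste0(sim$reads$pair_id, "/", m)
    qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
      strrep(qchar, n), character(1)))
    Biostrings::writeXStringSet(ss, sprintf("%s_%d.fastq", prefix, m),
                                format = "fastq", qualities = qual)
  }
  invisible(prefix)
}

#' Genome-space read blocks from a read simulation
#'
#' Expands every aligned mate into its genome-interval blocks (reads
#' spanning splice junctions contribute one block per exon touched).
#' This is the coverage-bearing representation consumed by
#' [coverage_curve()].
#'
#' @param sim a `ReadSimulation`.
#' @param truth the matching `TruthTable`.
#' @return data.table: `pair_id`, `seqname`, `start0`, `end0`.
#' @export
read_genome_blocks <- function(sim, truth) {
  rl <- sim$read_length
  aligned <- sim$reads[!is.na(tx_id)]
  iv <- rbind(
    aligned[, .(pair_id, tx_id, start0 = frag_start, end0 = frag_start + rl)],
    aligned[, .(pair_id, tx_id, start0 = frag_start + frag_len - rl,
                end0 = frag_start + frag_len)])
  bl <- tx_to_genome_blocks(truth$exons, iv)
  bl[, .(pair_id, seqname, start0, end0)]
}

#' Per-transcript read depth tracks
#'
#' Computes per-position read depth in transcript coordinates from the
#' simulated fragment placements (both mates of each pair contribute their
#' read-length footprint).
#'
#' @param sim a `ReadSimulation`.
#' @param tx_ids transcripts to compute (default: all with reads).
#' @param tx_lengths named vector of transcript lengths; defaults from the
#'   truth table attached to `sim` reads are not stored, so pass
#'   `truth$transcripts` lengths.
#' @param dedup drop duplicate-flagged pairs first.
#' @return named list of numeric depth vectors.
#' @export
transcript_depth <- function(sim, tx_lengths, tx_ids = NULL, dedup = FALSE) {
  rl <- sim$read_length
  rd <- sim$reads[!is.na(tx_id)]
  if (dedup) rd <- rd[duplicate == FALSE]
  if (!is.null(tx_ids)) rd <- rd[tx_id %in% tx_ids]
  ids <- if (is.null(tx_ids)) names(tx_lengths) else tx_ids
  iv <- rbind(rd[, .(tx_id, start0 = frag_start, end0 = frag_start + rl)],
              rd[, .(tx_id, start0 = frag_start + frag_len - rl,
                     end0 = frag_start + frag_len)])
  out <- lapply(stats::setNames(ids, ids), function(id)
    numeric(tx_lengths[[id]]))
  if (nrow(iv)) {
    sp <- split(iv, iv$tx_id)
    for (id in names(sp)) {
      cv <- IRanges::coverage(iranges0(sp[[id]]$start0, sp[[id]]$end0),
                              width = tx_lengths[[id]])
      out[[id]] <- as.numeric(cv)
    }
  }
  out
}
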