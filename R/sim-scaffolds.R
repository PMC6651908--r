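#' Simulate scaffolds with controlled completeness and chimerism
#'
#' Emits, per selected transcript, one scaffold covering a configured
#' fraction of its spliced sequence (1.0 = complete), optionally extended
#' by genomic UTR-like flanks beyond the annotated transcript ends, plus
#' optional chimeric scaffolds concatenating two transcripts.  PSL rows
#' reflect the true placements: per-exon blocks for ordinary scaffolds,
#' and one sub-threshold alignment per constituent for chimeras (so the
#' 98% single-alignment filter is guaranteed to flag them).
#'
#' @param genome a `GenomeModel`.
#' @param truth `TruthTable` from [simulate_genome_annotation()].
#' @param tx_ids transcripts to scaffold (default: all annotated).
#' @param fraction covered fraction of each transcript in (0,1]; scalar or
#'   vector along `tx_ids`.
#' @param flank bp of genomic sequence appended beyond each transcript end
#'   (emulating UTRs absent from the annotation); scalar.
#' @param n_chimera number of additional chimeric scaffolds joining random
#'   transcript pairs with a 60/40 length split.
#' @param seed seed (default derived from the truth's config seed).
#' @return list: `scaffolds` (named character), `psl` ([read_psl()]
#'   layout), `truth` (data.table: `scaffold_id`, `tx_id`, `fraction`,
#'   `chimeric`, `offset`).
#' @export
simulate_scaffolds <- function(genome, truth, tx_ids = NULL, fraction = 1,
                               flank = 0L, n_chimera = 0L,
                               seed = derive_seed(truth$config$seed,
                                                  "scaffolds")) {
  stopifnot(all(fraction > 0), all(fraction <= 1))
  with_seed(seed, .sim_scaffolds_impl(genome, truth, tx_ids, fraction,
                                      as.integer(flank), as.integer(n_chimera)))
}

.sim_scaffolds_impl <- function(genome, truth, tx_ids, fraction, flank,
                                n_chimera) {
  tr <- truth$transcripts
  if (is.null(tx_ids)) tx_ids <- tr[annotated == TRUE, tx_id]
  fraction <- rep_len(fraction, length(tx_ids))
  tx_seq <- transcript_sequences(genome, exons = truth$exons, tx_ids = tx_ids)
  tlen <- stats::setNames(tr$length_nt, tr$tx_id)

  scaffolds <- character(0)
  psl_rows <- list()
  truth_rows <- list()

  add_alignment <- function(q_name, q_size, tx, t_lo, t_hi, q_shift) {
    # genome blocks of transcript-space [t_lo, t_hi), query offset by q_shift
    bl <- tx_to_genome_blocks(
      truth$exons,
      data.table::data.table(tx_id = tx, start0 = t_lo, end0 = t_hi))
    data.table::setorder(bl, start0)
    st <- bl$strand[1L]
    # plus-frame query coordinate of each block
    qb <- q_shift + (bl$t_start0 - t_lo)
    sizes <- bl$end0 - bl$start0
    data.table::data.table(
      matches = sum(sizes), mismatches = 0L, rep_matches = 0L, n_count = 0L,
      strand = st, q_name = q_name, q_size = q_size,
      q_start = min(qb), q_end = max(qb + sizes),
      t_name = bl$seqname[1L],
      t_size = genome$lengths[[bl$seqname[1L]]],
      t_start = min(bl$start0), t_end = max(bl$end0),
      block_count = nrow(bl), block_sizes = list(sizes),
      q_starts = list(qb), t_starts = list(bl$start0),
      aligned_bases = sum(sizes),
      aligned_fraction = sum(sizes) / q_size)
  }

  for (i in seq_along(tx_ids)) {
    tx <- tx_ids[i]
    L <- tlen[[tx]]
    sl <- max(1L, as.integer(round(fraction[i] * L)))
    off <- if (sl < L) sample.int(L - sl + 1L, 1L) - 1L else 0L
    core <- substring(tx_seq[[tx]], off + 1L, off + sl)
    sid <- sprintf("scaf_%s", tx)

    f5 <- f3 <- ""
    fl5 <- fl3 <- 0L
    if (flank > 0L && fraction[i] >= 1) {
      # genomic sequence flanking the transcript in transcript orientation
      info <- tr[tx_id == tx]
      chrlen <- genome$lengths[[info$seqname]]
      if (info$strand == "+") {
        fl5 <- min(flank, info$start0)
        fl3 <- min(flank, chrlen - info$end0)
        if (fl5 > 0L) f5 <- genome_subseq(genome, info$seqname,
                                          info$start0 - fl5, info$start0)
        if (fl3 > 0L) f3 <- genome_subseq(genome, info$seqname, info$end0,
                                          info$end0 + fl3)
      } else {
        fl5 <- min(flank, chrlen - info$end0)
        fl3 <- min(flank, info$start0)
        if (fl5 > 0L) f5 <- revcomp(genome_subseq(genome, info$seqname,
                                                  info$end0, info$end0 + fl5))
        if (fl3 > 0L) f3 <- revcomp(genome_subseq(genome, info$seqname,
                                                  info$start0 - fl3,
                                                  info$start0))
      }
    }
    sseq <- paste0(f5, core, f3)
    q_size <- nchar(sseq)
    aln <- add_alignment(sid, q_size, tx, off, off + sl, fl5)
    if (fl5 > 0L || fl3 > 0L) {
      # extend with flank blocks (they are genomic, so they do align)
      info <- tr[tx_id == tx]
      extra <- list()
      if (info$strand == "+") {
        if (fl5 > 0L) extra <- c(extra, list(list(q = 0L,
          t = info$start0 - fl5, s = fl5)))
        if (fl3 > 0L) extra <- c(extra, list(list(q = q_size - fl3,
          t = info$end0, s = fl3)))
      } else {
        if (fl5 > 0L) extra <- c(extra, list(list(q = 0L,
          t = info$end0, s = fl5)))
        if (fl3 > 0L) extra <- c(extra, list(list(q = q_size - fl3,
          t = info$start0 - fl3, s = fl3)))
      }
      for (e in extra) {
        aln$block_sizes[[1L]] <- c(aln$block_sizes[[1L]], e$s)
        aln$q_starts[[1L]] <- c(aln$q_starts[[1L]], e$q)
        aln$t_starts[[1L]] <- c(aln$t_starts[[1L]], e$t)
      }
      o <- order(aln$t_starts[[1L]])
      aln$block_sizes[[1L]] <- aln$block_sizes[[1L]][o]
      aln$q_starts[[1L]] <- aln$q_starts[[1L]][o]
      aln$t_starts[[1L]] <- aln$t_starts[[1L]][o]
      aln[, `:=`(block_count = length(block_sizes[[1L]]),
                 matches = sum(block_sizes[[1L]]),
                 aligned_bases = sum(block_sizes[[1L]]),
                 aligned_fraction = sum(block_sizes[[1L]]) / q_size,
                 t_start = min(t_starts[[1L]]),
                 t_end = max(t_starts[[1L]] + block_sizes[[1L]]),
                 q_start = min(q_starts[[1L]]),
                 q_end = max(q_starts[[1L]] + block_sizes[[1L]]))]
    }
    scaffolds[sid] <- sseq
    psl_rows <- c(psl_rows, list(aln))
    truth_rows <- c(truth_rows, list(data.table::data.table(
      scaffold_id = sid, tx_id = tx, fraction = fraction[i],
      chimeric = FALSE, offset = off)))
  }

  if (n_chimera > 0L) {
    cand <- tr[annotated == TRUE & length_nt >= 200L]
    for (k in seq_len(n_chimera)) {
      pr <- cand[sample.int(nrow(cand), 2L)]
      # 60/40 split: take a prefix of tx A and a suffix of tx B sized so
      # neither single alignment can reach the 98% filter
      lenA <- as.integer(round(0.6 * pr$length_nt[1L]))
      lenB <- as.integer(round(0.4 * pr$length_nt[2L]))
      sid <- sprintf("chim_%03d_%s_%s", k, pr$tx_id[1L], pr$tx_id[2L])
      sA <- substring(tx_seq0(genome, truth, pr$tx_id[1L]), 1L, lenA)
      sB <- substring(tx_seq0(genome, truth, pr$tx_id[2L]), 1L, lenB)
      sseq <- paste0(sA, sB)
      q_size <- lenA + lenB
      a1 <- add_alignment(sid, q_size, pr$tx_id[1L], 0L, lenA, 0L)
      a2 <- add_alignment(sid, q_size, pr$tx_id[2L], 0L, lenB, lenA)
      scaffolds[sid] <- sseq
      psl_rows <- c(psl_rows, list(a1, a2))
      truth_rows <- c(truth_rows, list(data.table::data.table(
        scaffold_id = sid, tx_id = pr$tx_id, fraction = c(0.6, 0.4),
        chimeric = TRUE, offset = 0L)))
    }
  }

  list(scaffolds = scaffolds,
       psl = data.table::rbindlist(psl_rows),
       truth = data.table::rbindlist(truth_rows))
}

# spliced sequence of one transcript (memoised-free small helper)
tx_seq0 <- function(genome, truth, tx) {
  transcript_sequences(genome, exons = truth$exons, tx_ids = tx)[[tx]]
}
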