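#' Simulate a toy genome, annotation and ground truth
#'
#' Builds a genome of multi-exon genes separated by intergenic gaps, with
#' heterogeneous intron lengths, per-transcript GC targets and
#' exponentially distributed transcript abundances.  Optionally places
#' unannotated transcript templates in introns (the generative default for
#' "unprocessed pre-mRNA"-like material: unspliced, single-exon) or in
#' intergenic space; these are the low-abundance pool that drives continued
#' genomic (but not exomic) coverage gains at increasing sequencing depth.
#'
#' Deterministic for a given `cfg$seed`: two runs produce byte-identical
#' FASTA/GFF3 when written.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` ([genome_model()]), `annotation`
#'   ([annotation_set()], annotated genes only) and `truth`, a `TruthTable`
#'   list holding `transcripts` (id, annotated flag, placement, exon count,
#'   abundance, GC, true TPM), `exons` (exon map of all transcripts
#'   including unannotated templates) and the `config`.
#' @export
simulate_genome_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(derive_seed(cfg$seed, "genome"), .sim_genome_impl(cfg))
}

.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else as.integer(sample(seq(range[1], range[2]), n, replace = TRUE))
}

# Random sequence with an exact GC base count (uniform shuffle of a fixed
# composition); keeps the GC of every such unit on its target, so windowed
# GC measurements are noise-free.
.exact_gc_dna <- function(n, gc) {
  k <- round(gc * n)
  g <- k %/% 2L
  a <- (n - k) %/% 2L
  paste(sample(c(rep("G", g), rep("C", k - g), rep("A", a),
                 rep("T", n - k - a))), collapse = "")
}

# GC profile for a transcript of length L: constant or piecewise segments.
# Segmented profiles are built from 100 bp exact-composition units so that
# aligned 100 bp windows read back exactly the segment's GC level.
.tx_sequence <- function(L, cfg) {
  if (cfg$gc_profile == "constant") {
    random_dna(L, stats::runif(1, cfg$gc_mean[1], cfg$gc_mean[2]))
  } else {
    # stratified segment design: every transcript carries the same evenly
    # spaced GC levels in shuffled order, so per-transcript mean sampling
    # weight is constant under any fragment-level GC-bias function and the
    # windowed depth-ratio curve estimates that function without
    # composition confounding
    seg <- cfg$gc_segment_length
    n_seg <- ceiling(L / seg)
    lens <- c(rep(seg, n_seg - 1L), L - seg * (n_seg - 1L))
    levels <- if (n_seg == 1L) mean(cfg$gc_mean) else
      seq(cfg$gc_mean[1], cfg$gc_mean[2], length.out = n_seg)
    gcs <- sample(levels)
    paste(vapply(seq_along(lens), function(k) {
      l <- lens[k]
      units <- c(rep(100L, l %/% 100L), if (l %% 100L) l %% 100L)
      paste(vapply(units, .exact_gc_dna, character(1), gc = gcs[k]),
            collapse = "")
    }, character(1)), collapse = "")
  }
}

.sim_genome_impl <- function(cfg) {
  ng <- cfg$n_genes
  gene_chr <- rep(seq_len(cfg$n_chromosomes), length.out = ng)
  n_ex <- .runif_int(ng, cfg$exon_count)
  strands <- sample(c("+", "-"), ng, replace = TRUE)
  tx_ids <- sprintf("tx%04d", seq_len(ng))
  gene_ids <- sprintf("g%04d", seq_len(ng))

  exon_rows <- vector("list", ng)
  intron_rows <- vector("list", ng)
  spliced <- character(ng)
  pieces <- lapply(seq_len(cfg$n_chromosomes), function(i) list())
  pos <- integer(cfg$n_chromosomes)

  for (g in seq_len(ng)) {
    chr <- gene_chr[g]
    ex_len <- .runif_int(n_ex[g], cfg$exon_length)
    in_len <- if (n_ex[g] > 1L) .runif_int(n_ex[g] - 1L, cfg$intron_length)
              else integer(0)
    gap <- .runif_int(1L, cfg$intergenic_length)
    L <- sum(ex_len)
    S <- .tx_sequence(L, cfg)               # spliced sequence, 5'->3'
    # slice spliced sequence into transcription-order exons
    ends <- cumsum(ex_len)
    sl <- substring(S, ends - ex_len + 1L, ends)
    # genome order: ascending coordinates; for '-' genes the genome-first
    # exon is the transcription-last one, reverse-complemented
    gseq <- if (strands[g] == "+") sl else revcomp(rev(sl))
    glen <- if (strands[g] == "+") ex_len else rev(ex_len)

    start <- pos[chr] + gap
    coords <- integer(0)
    p <- start
    piece_seqs <- character(0)
    for (k in seq_len(n_ex[g])) {
      coords <- c(coords, p)
      piece_seqs <- c(piece_seqs, gseq[k])
      p <- p + glen[k]
      if (k < n_ex[g]) {
        piece_seqs <- c(piece_seqs, random_dna(in_len[k], cfg$background_gc))
        p <- p + in_len[k]
      }
    }
    pieces[[chr]] <- c(pieces[[chr]],
                       list(random_dna(gap, cfg$background_gc)),
                       as.list(piece_seqs))
    pos[chr] <- p
    rank <- if (strands[g] == "+") seq_len(n_ex[g]) else rev(seq_len(n_ex[g]))
    exon_rows[[g]] <- data.table::data.table(
      tx_id = tx_ids[g], gene_id = gene_ids[g],
      seqname = sprintf("chr%d", chr), strand = strands[g],
      start0 = coords, end0 = coords + glen, exon_rank = rank)
    if (n_ex[g] > 1L)
      intron_rows[[g]] <- data.table::data.table(
        tx_id = tx_ids[g], seqname = sprintf("chr%d", chr),
        start0 = coords[-n_ex[g]] + glen[-n_ex[g]], end0 = coords[-1L])
    spliced[g] <- S
  }
  # trailing intergenic tail per chromosome
  for (chr in seq_len(cfg$n_chromosomes)) {
    tail_len <- .runif_int(1L, cfg$intergenic_length)
    pieces[[chr]] <- c(pieces[[chr]],
                       list(random_dna(tail_len, cfg$background_gc)))
    pos[chr] <- pos[chr] + tail_len
  }
  chrom_seq <- vapply(pieces, function(p) paste(unlist(p), collapse = ""),
                      character(1))
  names(chrom_seq) <- sprintf("chr%d", seq_len(cfg$n_chromosomes))

  exons <- data.table::rbindlist(exon_rows)
  introns <- data.table::rbindlist(intron_rows[!vapply(intron_rows, is.null,
                                                       logical(1))])

  # --- unannotated templates -------------------------------------------
  margin <- 100L
  un_rows <- NULL
  if (cfg$n_unannotated > 0L) {
    hosts <- if (cfg$unannotated_placement == "intronic") {
      if (nrow(introns) == 0L)
        stop("intronic placement requested but the annotation has no introns")
      data.table::copy(introns)
    } else {
      # intergenic gaps: complement of gene spans
      spans <- exons[, .(start0 = min(start0), end0 = max(end0)),
                     by = .(gene_id, seqname)]
      gaps <- spans[, {
        s <- sort(start0); e <- sort(end0)
        list(start0 = c(0L, e), end0 = c(s, nchar(chrom_seq[[seqname[1]]])))
      }, by = seqname]
      gaps[end0 > start0][, tx_id := NA_character_][]
    }
    un_len <- .runif_int(cfg$n_unannotated, cfg$unannotated_length)
    ord <- order(un_len, decreasing = TRUE)
    hosts[, avail := end0 - start0 - 2L * margin]
    used <- rep(FALSE, nrow(hosts))
    un_list <- vector("list", cfg$n_unannotated)
    for (i in ord) {
      ok <- which(!used & hosts$avail >= un_len[i])
      if (length(ok) == 0L)
        stop("unannotated templates do not fit in the genome length budget;",
             " increase intron/intergenic lengths or reduce count/length")
      h <- ok[sample.int(length(ok), 1L)]
      used[h] <- TRUE
      off <- sample.int(hosts$avail[h] - un_len[i] + 1L, 1L) - 1L
      s0 <- hosts$start0[h] + margin + off
      un_list[[i]] <- data.table::data.table(
        seqname = hosts$seqname[h], start0 = s0, end0 = s0 + un_len[i])
    }
    un_rows <- data.table::rbindlist(un_list)
    un_rows[, tx_id := sprintf("utx%04d", seq_len(.N))]
    # overwrite host background with template sequence at its GC target
    for (i in seq_len(nrow(un_rows))) {
      tseq <- .tx_sequence(un_rows$end0[i] - un_rows$start0[i], cfg)
      substr(chrom_seq[[un_rows$seqname[i]]],
             un_rows$start0[i] + 1L, un_rows$end0[i]) <- tseq
    }
  }

  genome <- genome_model(chrom_seq)
  annotation <- annotation_set(exons, genome$lengths)

  all_exons <- data.table::copy(annotation$exons)
  tr <- data.table::copy(annotation$transcripts)
  tr[, `:=`(annotated = TRUE, intronic = FALSE)]
  if (!is.null(un_rows)) {
    un_ex <- un_rows[, .(tx_id, gene_id = tx_id, seqname, strand = "+",
                         start0, end0, exon_rank = 1L,
                         width0 = end0 - start0, cum_before = 0L)]
    all_exons <- rbind(all_exons, un_ex)
    un_tr <- un_rows[, .(tx_id, gene_id = tx_id, seqname, strand = "+",
                         start0, end0, n_exons = 1L,
                         length_nt = end0 - start0, annotated = FALSE,
                         intronic = cfg$unannotated_placement == "intronic")]
    tr <- rbind(tr, un_tr)
  }
  tx_seq <- transcript_sequences(genome, exons = all_exons)
  tr[, gc := gc_fraction(tx_seq[tx_id])]
  tr[, abundance := stats::rexp(.N, rate = cfg$abundance_rate) *
       ifelse(annotated, 1, cfg$unannotated_abundance_scale)]
  tr[, true_tpm := 1e6 * abundance / sum(abundance)]

  truth <- structure(list(transcripts = tr, exons = all_exons,
                          config = cfg), class = "TruthTable")
  list(genome = genome, annotation = annotation, truth = truth)
}
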