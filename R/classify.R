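#' Classification parameters
#'
#' @param threshold_grid annotation-threshold grid in percent.
#' @param min_intron_gap minimum target-side alignment gap (bp) counted as
#'   an intron; smaller gaps are treated as indels.
#' @param max_query_gap maximum query-side gap (bp) for a target gap to
#'   count as an intron (an intron consumes no query sequence).
#' @param orf_min_scaffold minimum scaffold length (bp) to enter the ORF
#'   denominator.
#' @param orf_min_aa minimum ORF length in amino acids.
#' @param intronic_majority fraction of aligned bases that must fall in
#'   the global intron union for an intronic call (strict inequality;
#'   exact ties are non-intronic).
#' @return list of class `ClassificationParams`.
#' @export
classification_params <- function(threshold_grid = 0:100,
                                  min_intron_gap = 30L,
                                  max_query_gap = 10L,
                                  orf_min_scaffold = 300L,
                                  orf_min_aa = 100L,
                                  intronic_majority = 0.5) {
  stopifnot(all(threshold_grid >= 0), all(threshold_grid <= 100),
            min_intron_gap > 0L, orf_min_scaffold > 0L, orf_min_aa > 0L,
            intronic_majority >= 0, intronic_majority <= 1)
  structure(list(threshold_grid = as.integer(threshold_grid),
                 min_intron_gap = as.integer(min_intron_gap),
                 max_query_gap = as.integer(max_query_gap),
                 orf_min_scaffold = as.integer(orf_min_scaffold),
                 orf_min_aa = as.integer(orf_min_aa),
                 intronic_majority = intronic_majority),
            class = "ClassificationParams")
}

#' Annotation fraction of scaffolds against reference transcripts
#'
#' For each scaffold alignment and each overlapping transcript, the
#' overlap is the number of aligned bases falling in that transcript's
#' exon set; the annotation fraction is
#' `max(overlap / scaffold_length, overlap / transcript_length)` -- the
#' denominator is whichever is more favorable, so a short scaffold fully
#' inside a long transcript and a full-length scaffold with extra UTR
#' sequence both score high.  Per scaffold the maximizing transcript is
#' recorded.
#'
#' @param psl retained alignments ([read_psl()] layout).
#' @param annotation an `AnnotationSet`.
#' @return data.table: `q_name`, `best_tx`, `overlap_bases`,
#'   `frac_scaffold`, `frac_transcript`, `fraction` (the max); scaffolds
#'   with no exon overlap get fraction 0 and `best_tx` NA.
#' @export
annotation_fraction <- function(psl, annotation) {
  psl <- data.table::as.data.table(psl)
  all_scaf <- unique(psl$q_name)
  empty <- data.table::data.table(
    q_name = all_scaf, best_tx = NA_character_, overlap_bases = 0L,
    frac_scaffold = 0, frac_transcript = 0, fraction = 0)
  if (nrow(psl) == 0L) return(empty[0L])
  bl <- psl_blocks(psl)
  hits <- genome_blocks_to_tx(annotation$exons, bl)
  if (nrow(hits) == 0L) return(empty)
  ov <- hits[, .(overlap_bases = {
    sum(IRanges::width(IRanges::reduce(iranges0(t_start0, t_end0))))
  }), by = .(q_name, tx_id)]
  sizes <- unique(psl[, .(q_name, q_size)])
  tlen <- annotation$transcripts[, .(tx_id, tx_len = length_nt)]
  ov <- tlen[ov, on = "tx_id"]
  ov <- sizes[ov, on = "q_name"]
  ov[, `:=`(frac_scaffold = overlap_bases / q_size,
            frac_transcript = overlap_bases / tx_len)]
  ov[, fraction := pmax(frac_scaffold, frac_transcript)]
  data.table::setorder(ov, q_name, -fraction, tx_id)
  best <- ov[, .SD[1L], by = q_name]
  best <- best[, .(q_name, best_tx = tx_id, overlap_bases, frac_scaffold,
                   frac_transcript, fraction)]
  miss <- setdiff(all_scaf, best$q_name)
  if (length(miss)) best <- rbind(best, empty[q_name %in% miss])
  best[]
}

#' Annotated/unannotated partition over a threshold grid
#'
#' A scaffold is annotated at threshold `t` iff its annotation fraction is
#' strictly greater than `t/100`.  The annotated count is therefore
#' monotone non-increasing along the grid.
#'
#' @param fractions output of [annotation_fraction()].
#' @param threshold_grid integer percent grid.
#' @return data.table: `threshold`, `n_annotated`, `n_unannotated`.
#' @export
classify_annotated <- function(fractions, threshold_grid = 0:100) {
  fr <- data.table::as.data.table(fractions)
  data.table::rbindlist(lapply(as.integer(threshold_grid), function(t) {
    ann <- fr$fraction > t / 100
    data.table::data.table(threshold = t, n_annotated = sum(ann),
                           n_unannotated = sum(!ann))
  }))
}

#' Exon structure of a scaffold alignment
#'
#' Adjacent target blocks separated by a target-side gap of at least
#' `min_intron_gap` bases (with essentially no query-side gap) are exon
#' boundaries; smaller gaps are treated as assembly/alignment indels.
#'
#' @param psl alignments ([read_psl()] layout), one row per alignment.
#' @param min_intron_gap,max_query_gap see [classification_params()].
#' @return data.table: `q_name`, `exon_count`, `single_exon`.
#' @export
exon_structure <- function(psl, min_intron_gap = 30L, max_query_gap = 10L) {
  psl <- data.table::as.data.table(psl)
  n_introns <- vapply(seq_len(nrow(psl)), function(i) {
    sz <- psl$block_sizes[[i]]; ts <- psl$t_starts[[i]]
    qs <- psl$q_starts[[i]]
    if (length(sz) < 2L) return(0L)
    o <- order(ts)
    sz <- sz[o]; ts <- ts[o]; qs <- qs[o]
    t_gap <- ts[-1L] - (ts[-length(ts)] + sz[-length(sz)])
    # query gap between consecutive target blocks, in the plus query frame;
    # for minus-strand alignments query intervals descend with target order
    q_gap <- if (psl$strand[i] == "+")
      qs[-1L] - (qs[-length(qs)] + sz[-length(sz)])
    else qs[-length(qs)] - (qs[-1L] + sz[-1L])
    sum(t_gap >= min_intron_gap & abs(q_gap) <= max_query_gap)
  }, integer(1))
  data.table::data.table(q_name = psl$q_name,
                         exon_count = 1L + n_introns,
                         single_exon = n_introns == 0L)
}

#' Intronic classification of unannotated single-exon scaffolds
#'
#' A scaffold is intronic when strictly more than `majority` of its
#' aligned target bases fall within the global intron union.  The
#' aggregate SEI is the intronic fraction among the supplied scaffolds.
#'
#' @param psl alignments of the unannotated single-exon scaffolds.
#' @param annotation an `AnnotationSet`.
#' @param majority majority fraction (strict).
#' @return list: `records` (data.table `q_name`, `intronic_bases`,
#'   `aligned_bases`, `intronic`), `sei` (aggregate fraction, NA when no
#'   scaffolds).
#' @export
classify_intronic <- function(psl, annotation, majority = 0.5) {
  psl <- data.table::as.data.table(psl)
  if (nrow(psl) == 0L)
    return(list(records = data.table::data.table(
      q_name = character(0), intronic_bases = integer(0),
      aligned_bases = integer(0), intronic = logical(0)), sei = NA_real_))
  bl <- psl_blocks(psl)
  per <- bl[, .(intronic_bases = sum(IRanges::width(
    GenomicRanges::intersect(IRanges::reduce(granges0(.SD)),
                             annotation$intron_union,
                             ignore.strand = TRUE)))),
    by = q_name, .SDcols = c("seqname", "start0", "end0")]
  rec <- bl[, .(aligned_bases = sum(end0 - start0)), by = q_name]
  rec <- per[rec, on = "q_name"]
  rec[is.na(intronic_bases), intronic_bases := 0L]
  rec[, intronic := intronic_bases / aligned_bases > majority]
  list(records = rec[], sei = mean(rec$intronic))
}

#' Full scaffold classification
#'
#' Combines alignment filtering output into the per-scaffold record table:
#' annotation fraction and best transcript, exon count and single-exon
#' flag, intronic flag (for unannotated single-exon scaffolds at the
#' designated threshold), and ORF flag (scaffolds shorter than
#' `orf_min_scaffold` are excluded from ORF denominators).  Also returns
#' the per-threshold sweep summary.
#'
#' @param psl retained best-hit alignments.
#' @param annotation an `AnnotationSet`.
#' @param scaffold_seqs named character vector of scaffold sequences (for
#'   the ORF scan); optional.
#' @param params a [classification_params()].
#' @param at designated threshold (percent) for the SE/SEI/ORF summary.
#' @return list: `records` (per-scaffold data.table), `sweep`
#'   (per-threshold partition), `summary` (one-row data.table at the
#'   designated threshold: `threshold`, `n_annotated`, `n_unannotated`,
#'   `se_annotated`, `se_unannotated`, `sei`, `orf_annotated`,
#'   `orf_unannotated`).
#' @export
classify_scaffolds <- function(psl, annotation, scaffold_seqs = NULL,
                               params = classification_params(), at = 80L) {
  fr <- annotation_fraction(psl, annotation)
  es <- exon_structure(psl, params$min_intron_gap, params$max_query_gap)
  rec <- es[fr, on = "q_name"]
  rec[, annotated := fraction > at / 100]
  un_se <- rec[annotated == FALSE & single_exon == TRUE, q_name]
  ci <- classify_intronic(psl[q_name %in% un_se], annotation,
                          params$intronic_majority)
  rec[, intronic := FALSE]
  rec[q_name %in% ci$records[intronic == TRUE, q_name], intronic := TRUE]
  if (!is.null(scaffold_seqs)) {
    orf <- find_orfs(scaffold_seqs, min_aa = params$orf_min_aa)
    orf_dt <- data.table::data.table(q_name = orf$id,
                                     longest_orf_aa = orf$longest_orf_aa,
                                     has_orf = orf$has_orf,
                                     scaffold_len = nchar(scaffold_seqs[orf$id]))
    rec <- orf_dt[rec, on = "q_name"]
  }
  sweep <- classify_annotated(fr, params$threshold_grid)
  smry <- data.table::data.table(
    threshold = at,
    n_annotated = sum(rec$annotated),
    n_unannotated = sum(!rec$annotated),
    se_annotated = mean(rec[annotated == TRUE, single_exon]),
    se_unannotated = mean(rec[annotated == FALSE, single_exon]),
    sei = ci$sei)
  if (!is.null(scaffold_seqs)) {
    big <- rec[scaffold_len >= params$orf_min_scaffold]
    smry[, `:=`(orf_annotated = mean(big[annotated == TRUE, has_orf]),
                orf_unannotated = mean(big[annotated == FALSE, has_orf]))]
  }
  list(records = rec[], sweep = sweep, summary = smry)
}
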