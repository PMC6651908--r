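#' Completeness parameters
#'
#' @param min_fraction minimum fraction of a reference transcript that a
#'   single scaffold's top alignment must cover (default 0.95, `>=`).
#' @param unambiguous_top require the scaffold's best alignment score to
#'   be strictly greater than its second best; scaffolds with tied top
#'   hits are discarded.
#' @return list of class `CompletenessParams`.
#' @export
completeness_params <- function(min_fraction = 0.95,
                                unambiguous_top = TRUE) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  structure(list(min_fraction = min_fraction,
                 unambiguous_top = isTRUE(unambiguous_top)),
            class = "CompletenessParams")
}

#' Project genome-space scaffold alignments into transcript space
#'
#' Derives scaffold-vs-transcript alignments from genome PSL rows by
#' intersecting target blocks with each transcript's exons and mapping to
#' spliced-transcript coordinates.  The alignment score is the total
#' number of projected bases (block-length total).
#'
#' @param psl alignments in [read_psl()] layout.
#' @param annotation an `AnnotationSet`.
#' @return data.table: `q_name`, `tx_id`, `t_start0`, `t_end0` (one row
#'   per projected interval, transcript space).
#' @export
project_to_transcripts <- function(psl, annotation) {
  bl <- psl_blocks(psl)
  genome_blocks_to_tx(annotation$exons, bl)[
    , .(q_name, tx_id, t_start0, t_end0)]
}

#' Complete transcripts under the single-scaffold rule
#'
#' A reference transcript is complete when some scaffold, whose top-scoring
#' alignment is unambiguous (strictly better than its second best), covers
#' at least `min_fraction` of the transcript length with that single
#' alignment.  Covered fraction is the union of aligned transcript
#' positions of the top alignment, so internal gaps do not count.
#' Aligned intervals extending past the transcript end (UTR-bearing
#' scaffolds) are clamped with a warning.
#'
#' @param txaln transcript-space alignments (`q_name`, `tx_id`,
#'   `t_start0`, `t_end0`), e.g. from [project_to_transcripts()].
#' @param tx_lengths named vector of transcript lengths.
#' @param params a [completeness_params()].
#' @return character vector of complete transcript ids (sorted).
#' @export
complete_transcripts <- function(txaln, tx_lengths,
                                 params = completeness_params()) {
  ta <- data.table::as.data.table(txaln)
  if (nrow(ta) == 0L) return(character(0))
  if (any(ta$t_end0 > tx_lengths[ta$tx_id])) {
    warning("alignment interval(s) beyond transcript end clamped")
    ta[, t_end0 := pmin(t_end0, tx_lengths[tx_id])]
    ta <- ta[t_end0 > t_start0]
  }
  sc <- ta[, .(score = sum(IRanges::width(IRanges::reduce(
    iranges0(t_start0, t_end0))))), by = .(q_name, tx_id)]
  data.table::setorder(sc, q_name, -score, tx_id)
  top <- sc[, .SD[score == max(score)], by = q_name]
  if (params$unambiguous_top) {
    # a tied top score disqualifies the scaffold entirely
    top <- top[, if (.N == 1L) .SD, by = q_name]
  }
  cand <- ta[top[, .(q_name, tx_id)], on = c("q_name", "tx_id"),
             nomatch = NULL]
  cov <- cand[, .(covered = sum(IRanges::width(IRanges::reduce(
    iranges0(t_start0, t_end0))))), by = .(q_name, tx_id)]
  cov[, frac := covered / tx_lengths[tx_id]]
  sort(unique(cov[frac >= params$min_fraction, tx_id]))
}

#' Complete-transcript counts across nested subsample sizes
#'
#' Emulates assembly per subsample: a transcript's scaffold is taken to be
#' its longest contiguous read-covered run in transcript space (a de novo
#' assembler cannot join across a zero-coverage gap), and the transcript is
#' complete when that single run covers at least `min_fraction` of its
#' length.  Nested subsets (prefixes of one seeded permutation) make the
#' counts monotone non-decreasing in size.
#'
#' @param sim a `ReadSimulation`.
#' @param truth matching `TruthTable`.
#' @param sizes ascending target base counts.
#' @param seed subsampling seed.
#' @param params a [completeness_params()].
#' @param annotated_only restrict to annotated transcripts.
#' @return list: `counts` (data.table `size_bp`, `n_complete`),
#'   `complete_sets` (list of id vectors per size).
#' @export
completeness_by_size <- function(sim, truth, sizes, seed,
                                 params = completeness_params(),
                                 annotated_only = TRUE) {
  rl <- sim$read_length
  rd <- sim$reads[!is.na(tx_id)]
  if (annotated_only)
    rd <- rd[tx_id %in% truth$transcripts[annotated == TRUE, tx_id]]
  tlen <- stats::setNames(truth$transcripts$length_nt,
                          truth$transcripts$tx_id)
  perm <- subsample_permutation(nrow(rd), seed)
  cum <- cumsum(rep(2 * rl, nrow(rd)))
  sets <- lapply(sizes, function(sz) {
    k <- if (cum[length(cum)] < sz) nrow(rd) else which(cum >= sz)[1L]
    sub <- rd[perm[seq_len(k)]]
    iv <- rbind(sub[, .(tx_id, start0 = frag_start,
                        end0 = frag_start + rl)],
                sub[, .(tx_id, start0 = frag_start + frag_len - rl,
                        end0 = frag_start + frag_len)])
    runs <- merge_intervals(iv, by = "tx_id")
    best <- runs[, .(run_len = max(end0 - start0)), by = tx_id]
    best[, frac := run_len / tlen[tx_id]]
    sort(best[frac >= params$min_fraction, tx_id])
  })
  list(counts = data.table::data.table(size_bp = sizes,
                                       n_complete = lengths(sets)),
       complete_sets = sets)
}

#' Row-normalized overlap matrix of complete-transcript sets
#'
#' Entry (r, c) is the number of complete transcripts shared between
#' libraries r and c divided by the total number of complete transcripts
#' of the row library; the matrix is generally asymmetric.  Rows with an
#' empty complete set are reported as NA (undefined), not 0.
#'
#' @param complete_sets named list of complete transcript id vectors.
#' @return numeric matrix of class `OverlapMatrix`.
#' @export
overlap_matrix <- function(complete_sets) {
  if (length(complete_sets) < 2L) stop("need at least two libraries")
  nm <- names(complete_sets) %||% paste0("lib", seq_along(complete_sets))
  n <- length(complete_sets)
  m <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (r in seq_len(n)) {
    if (length(complete_sets[[r]]) == 0L) next
    for (c in seq_len(n))
      m[r, c] <- length(intersect(complete_sets[[r]], complete_sets[[c]])) /
        length(complete_sets[[r]])
  }
  class(m) <- c("OverlapMatrix", class(m))
  m
}
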