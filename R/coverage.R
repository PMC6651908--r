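#' Scaffold alignment filter parameters
#'
#' @param min_fraction minimum aligned-query-fraction a scaffold's single
#'   best alignment must reach to be retained (default 0.98, applied as a
#'   `>=` threshold).
#' @param best_hit_only keep only the best alignment of each retained
#'   scaffold downstream, so multi-mapping scaffolds never double-count
#'   genome bases.
#' @return list of class `AlignmentFilterParams`.
#' @export
alignment_filter_params <- function(min_fraction = 0.98,
                                    best_hit_only = TRUE) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  structure(list(min_fraction = min_fraction,
                 best_hit_only = isTRUE(best_hit_only)),
            class = "AlignmentFilterParams")
}

#' Filter scaffold-to-genome alignments for quality and chimerism
#'
#' A scaffold is `retained` when its single best alignment (most matched
#' bases; ties broken by fewest blocks, then lexicographic target name)
#' covers at least `min_fraction` of the scaffold length, counting summed
#' block lengths of that one alignment.  Scaffolds whose union of
#' alignments reaches the fraction while no single alignment does are
#' `chimeric`; the rest are `low_quality`.  Every input scaffold receives
#' exactly one verdict.
#'
#' @param psl alignments in [read_psl()] layout.
#' @param params an [alignment_filter_params()].
#' @return list: `alignments` (retained rows; only the best per scaffold
#'   when `best_hit_only`), `verdicts` (data.table `q_name`, `verdict`,
#'   `best_fraction`, `union_fraction`).
#' @export
filter_alignments <- function(psl, params = alignment_filter_params()) {
  psl <- data.table::as.data.table(psl)
  if (nrow(psl) == 0L)
    return(list(alignments = psl,
                verdicts = data.table::data.table(
                  q_name = character(0), verdict = character(0),
                  best_fraction = numeric(0), union_fraction = numeric(0))))
  psl[, aln_id := .I]
  data.table::setorder(psl, q_name, -matches, block_count, t_name)
  best <- psl[, .SD[1L], by = q_name]
  # union of aligned query intervals across all alignments of a scaffold
  uni <- psl[, {
    iv <- IRanges::reduce(iranges0(unlist(q_starts),
                                   unlist(q_starts) + unlist(block_sizes)))
    list(union_bases = sum(IRanges::width(iv)), q_size = q_size[1L])
  }, by = q_name]
  v <- best[, .(q_name, best_fraction = aligned_fraction,
                best_aln = aln_id)]
  v <- uni[v, on = "q_name"]
  v[, union_fraction := union_bases / q_size]
  v[, verdict := data.table::fifelse(
    best_fraction >= params$min_fraction, "retained",
    data.table::fifelse(union_fraction >= params$min_fraction,
                        "chimeric", "low_quality"))]
  keep <- v[verdict == "retained"]
  aln <- if (params$best_hit_only) psl[aln_id %in% keep$best_aln]
         else psl[q_name %in% keep$q_name]
  aln[, aln_id := NULL]
  list(alignments = aln[],
       verdicts = v[, .(q_name, verdict, best_fraction, union_fraction)])
}

#' Unique genome and exome bases covered by alignments
#'
#' Counts every genome position covered by at least one aligned target
#' block exactly once; the exome count intersects that union with the
#' annotation's global exon union.
#'
#' @param psl retained alignments ([read_psl()] layout).
#' @param annotation an `AnnotationSet`, or `NULL` to skip the exome track.
#' @return list with `genome_bases` and `exome_bases` (NA when no
#'   annotation is supplied).
#' @export
unique_base_coverage <- function(psl, annotation = NULL) {
  if (nrow(psl) == 0L)
    return(list(genome_bases = 0L,
                exome_bases = if (is.null(annotation)) NA_integer_ else 0L))
  bl <- psl_blocks(psl)
  if (!is.null(annotation)) {
    bad <- setdiff(unique(bl$seqname), names(annotation$seqlengths))
    if (length(bad))
      stop("alignment on unknown sequence(s): ", paste(bad, collapse = ", "))
    if (any(bl$end0 > annotation$seqlengths[bl$seqname]))
      stop("alignment block off the end of a sequence")
  }
  gr <- IRanges::reduce(granges0(bl))
  genome_bases <- sum(IRanges::width(gr))
  exome_bases <- if (is.null(annotation)) NA_integer_ else
    sum(IRanges::width(GenomicRanges::intersect(gr, annotation$exon_union,
                                                ignore.strand = TRUE)))
  list(genome_bases = genome_bases, exome_bases = exome_bases)
}

#' Genome/exome unique-base coverage curve over nested subsamples
#'
#' Draws nested subsamples of read pairs (prefixes of one seeded
#' permutation, so coverage is monotone non-decreasing in subsample size),
#' emulates assembly by taking the genome regions covered by at least
#' `min_depth` reads in the subsample, and counts unique genome and exome
#' bases.  The final column normalizes every value by the exome coverage of
#' the largest subsample (by the genome coverage when no annotation is
#' given).
#'
#' @param pairs data.table with `pair_id` and `n_bases`.
#' @param blocks genome-space read blocks (`pair_id`, `seqname`, `start0`,
#'   `end0`), e.g. from [read_genome_blocks()].
#' @param sizes ascending target base counts.
#' @param seed subsampling seed.
#' @param annotation an `AnnotationSet` or `NULL`.
#' @param min_depth minimum read depth for a position to count as
#'   assembled (the assembly stand-in; 1 = plain coverage union).
#' @return data.table: `size_bp`, `n_pairs`, `genome_bases`,
#'   (`exome_bases`), `genome_norm`, (`exome_norm`).
#' @export
coverage_curve <- function(pairs, blocks, sizes, seed, annotation = NULL,
                           min_depth = 1L) {
  if (length(sizes) == 0L) stop("empty size list")
  stopifnot(!is.unsorted(sizes))
  p <- data.table::as.data.table(pairs)
  bl <- data.table::as.data.table(blocks)
  perm <- subsample_permutation(nrow(p), seed)
  cum <- cumsum(as.numeric(p$n_bases[perm]))
  total <- cum[length(cum)]

  rows <- lapply(sizes, function(sz) {
    if (total < sz) {
      warning("library smaller than target ", sz,
              " bases; using the entire library")
      k <- nrow(p)
    } else k <- which(cum >= sz)[1L]
    ids <- p$pair_id[perm[seq_len(k)]]
    sub <- bl[pair_id %in% ids]
    if (min_depth <= 1L) {
      gr <- IRanges::reduce(granges0(sub))
    } else {
      cov <- GenomicRanges::coverage(granges0(sub))
      gr <- GenomicRanges::GRanges(IRanges::slice(cov, lower = min_depth,
                                                  rangesOnly = TRUE))
    }
    genome_bases <- sum(as.numeric(IRanges::width(gr)))
    exome_bases <- if (is.null(annotation)) NA_real_ else
      sum(as.numeric(IRanges::width(
        GenomicRanges::intersect(gr, annotation$exon_union,
                                 ignore.strand = TRUE))))
    data.table::data.table(size_bp = sz, n_pairs = k,
                           genome_bases = genome_bases,
                           exome_bases = exome_bases)
  })
  out <- data.table::rbindlist(rows)
  denom <- if (is.null(annotation)) out$genome_bases[nrow(out)]
           else out$exome_bases[nrow(out)]
  out[, genome_norm := genome_bases / denom]
  if (!is.null(annotation)) out[, exome_norm := exome_bases / denom]
  else out[, exome_bases := NULL]
  out[]
}
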