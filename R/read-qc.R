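#' Read-filtering thresholds
#'
#' Defaults implement the standard short-read cleaning rule set: a pair is
#' dropped when either mate has more than 10% of bases below PHRED 10,
#' more than 1% ambiguous Ns ("more than" is strict in both cases), or
#' carries at least 50% of an adapter with at most one mismatch.  Adapter
#' matching is anchored read-through geometry: the match must start at the
#' adapter's 5' end and run to the read's 3' end.
#'
#' @param phred_cutoff low-quality PHRED cutoff.
#' @param max_low_frac maximum tolerated fraction of low-quality bases.
#' @param max_n_frac maximum tolerated fraction of ambiguous bases.
#' @param adapters character vector of adapter sequences.
#' @param min_adapter_frac minimum fraction of the adapter that must match.
#' @param max_adapter_mismatch maximum mismatches in the adapter match.
#' @return list of class `QcThresholds`.
#' @export
qc_thresholds <- function(phred_cutoff = 10L, max_low_frac = 0.10,
                          max_n_frac = 0.01, adapters = character(0),
                          min_adapter_frac = 0.5, max_adapter_mismatch = 1L) {
  stopifnot(phred_cutoff >= 0, max_low_frac >= 0, max_low_frac <= 1,
            max_n_frac >= 0, max_n_frac <= 1,
            min_adapter_frac >= 0, min_adapter_frac <= 1,
            max_adapter_mismatch >= 0)
  structure(list(phred_cutoff = as.integer(phred_cutoff),
                 max_low_frac = max_low_frac, max_n_frac = max_n_frac,
                 adapters = toupper(adapters),
                 min_adapter_frac = min_adapter_frac,
                 max_adapter_mismatch = as.integer(max_adapter_mismatch)),
            class = "QcThresholds")
}

# Anchored adapter detection: does a prefix of `adapter` of length
# >= ceil(min_frac * nchar(adapter)) match the 3' end of the read with at
# most `max_mm` mismatches?  Vectorized over reads.
.adapter_hit <- function(seqs, adapter, min_frac, max_mm) {
  m <- nchar(adapter)
  len <- nchar(seqs)
  min_k <- max(1L, as.integer(ceiling(min_frac * m)))
  hit <- rep(FALSE, length(seqs))
  for (k in seq(min_k, m)) {
    idx <- which(!hit & len >= k)
    if (length(idx) == 0L) next
    suf <- substring(seqs[idx], len[idx] - k + 1L, len[idx])
    pre <- substr(adapter, 1L, k)
    mm <- integer(length(idx))
    for (j in seq_len(k))
      mm <- mm + (substring(suf, j, j) != substring(pre, j, j))
    hit[idx[mm <= max_mm]] <- TRUE
  }
  hit
}

# Per-read rule verdicts; quals is a list of integer PHRED vectors.
.read_flags <- function(seqs, quals, t) {
  len <- nchar(seqs)
  if (any(len == 0L)) stop("empty read")
  low <- vapply(seq_along(seqs), function(i)
    sum(quals[[i]] < t$phred_cutoff) / len[i], numeric(1))
  nfrac <- vapply(gregexpr("N", seqs, fixed = TRUE), function(p)
    sum(p > 0L), integer(1)) / len
  adap <- rep(FALSE, length(seqs))
  for (a in t$adapters)
    adap <- adap | .adapter_hit(seqs, a, t$min_adapter_frac,
                                t$max_adapter_mismatch)
  list(adapter = adap, low_quality = low > t$max_low_frac,
       ambiguous = nfrac > t$max_n_frac)
}

#' Filter read pairs by quality rules
#'
#' A pair is dropped if either mate trips any rule; the recorded category
#' is the first tripped rule in the order adapter, low-quality, ambiguous.
#'
#' @param pairs data.table with `pair_id`, `seq1`, `seq2` and quality
#'   list-columns `qual1`, `qual2` (integer PHRED vectors).  A scalar
#'   `quality` attribute-free shortcut: pass `constant_quality` to fill
#'   uniform qualities.
#' @param thresholds a [qc_thresholds()].
#' @param constant_quality optional scalar PHRED filling `qual1`/`qual2`
#'   when absent (simulated error-free reads).
#' @return data.table `pair_id`, `verdict` (factor: `keep`,
#'   `drop:adapter`, `drop:low_quality`, `drop:ambiguous`).
#' @export
filter_read_pairs <- function(pairs, thresholds,
                              constant_quality = NULL) {
  p <- data.table::as.data.table(pairs)
  if (!all(c("qual1", "qual2") %in% names(p))) {
    if (is.null(constant_quality))
      stop("pairs need qual1/qual2 list-columns or constant_quality")
    p[, qual1 := lapply(nchar(seq1), function(n)
      rep(as.integer(constant_quality), n))]
    p[, qual2 := lapply(nchar(seq2), function(n)
      rep(as.integer(constant_quality), n))]
  }
  f1 <- .read_flags(p$seq1, p$qual1, thresholds)
  f2 <- .read_flags(p$seq2, p$qual2, thresholds)
  verdict <- rep("keep", nrow(p))
  verdict[f1$ambiguous | f2$ambiguous] <- "drop:ambiguous"
  verdict[f1$low_quality | f2$low_quality] <- "drop:low_quality"
  verdict[f1$adapter | f2$adapter] <- "drop:adapter"
  data.table::data.table(pair_id = p$pair_id,
                         verdict = factor(verdict,
                                          levels = c("keep", "drop:adapter",
                                                     "drop:low_quality",
                                                     "drop:ambiguous")))
}

#' Filter one read pair
#'
#' Scalar convenience wrapper around [filter_read_pairs()].
#'
#' @param seq1,seq2 mate sequences.
#' @param qual1,qual2 integer PHRED vectors.
#' @param thresholds a [qc_thresholds()].
#' @return single verdict string.
#' @export
filter_read_pair <- function(seq1, qual1, seq2, qual2, thresholds) {
  as.character(filter_read_pairs(
    data.table::data.table(pair_id = "p", seq1 = seq1, seq2 = seq2,
                           qual1 = list(as.integer(qual1)),
                           qual2 = list(as.integer(qual2))),
    thresholds)$verdict)
}

#' Clean-pair filter on mapped placements
#'
#' Keeps pairs whose two mates are on the same sequence, in convergent
#' (forward/reverse) orientation, with leftmost-coordinate span at most
#' `max_span`.  Unpaired records (missing a mate coordinate) are counted,
#' excluded and reported via a message.
#'
#' @param placements data.table with `pair_id`, `seqname`, `pos1`, `pos2`,
#'   `strand1`, `strand2`; an optional `seqname2` column carries mate 2's
#'   sequence when it differs (such pairs are inconsistent in location and
#'   removed).
#' @param max_span maximum allowed distance between mate leftmost
#'   coordinates.
#' @return character vector of kept pair identifiers.
#' @export
clean_pair_filter <- function(placements, max_span = 10000L) {
  pl <- data.table::as.data.table(placements)
  unpaired <- pl[is.na(pos1) | is.na(pos2) | is.na(seqname)]
  if (nrow(unpaired))
    message(nrow(unpaired), " unpaired record(s) excluded")
  pl <- pl[!is.na(pos1) & !is.na(pos2) & !is.na(seqname)]
  same_seq <- if ("seqname2" %in% names(pl))
    is.na(pl$seqname2) | pl$seqname2 == pl$seqname else TRUE
  # convergent: opposite strands with the forward mate leftmost
  fwd_pos <- data.table::fifelse(pl$strand1 == "+", pl$pos1, pl$pos2)
  rev_pos <- data.table::fifelse(pl$strand1 == "+", pl$pos2, pl$pos1)
  ok <- same_seq & pl$strand1 != pl$strand2 & fwd_pos <= rev_pos &
    (rev_pos - fwd_pos) <= max_span
  pl$pair_id[ok]
}

#' Collapse PCR duplicates
#'
#' Pairs sharing (sequence, mate-1 coordinate and strand, mate-2 coordinate
#' and strand) are collapsed to one representative, the lexicographically
#' smallest pair identifier.  Idempotent.
#'
#' @param placements data.table with `pair_id`, `seqname`, `pos1`,
#'   `strand1`, `pos2`, `strand2`.
#' @return character vector of kept pair identifiers.
#' @export
deduplicate <- function(placements) {
  pl <- data.table::as.data.table(placements)
  if (nrow(pl) == 0L) return(character(0))
  pl[, .(pair_id = min(pair_id)),
     by = .(seqname, pos1, strand1, pos2, strand2)]$pair_id
}

#' Random permutation of a pair library for nested subsampling
#'
#' Subsets obtained by truncating one seeded permutation are nested:
#' the prefix reaching 2 Gbp is a strict subset of the prefix reaching
#' 4 Gbp.  [subsample_to_bases()] and [coverage_curve()] build on this.
#'
#' @param n number of pairs.
#' @param seed seed.
#' @return integer permutation of `seq_len(n)`.
#' @export
subsample_permutation <- function(n, seed) {
  with_seed(seed, sample.int(n))
}

#' Subsample whole read pairs to a target base count
#'
#' Uniform sampling without replacement of whole pairs until the cumulative
#' base count reaches the target; the first pair crossing the target is
#' included.  If the library is smaller than the target the entire library
#' is returned with a warning.
#'
#' @param pairs data.table with `pair_id` and `n_bases` per pair.
#' @param target_bases target cumulative base count (> 0).
#' @param seed seed.
#' @return data.table subset of `pairs` (original row order preserved).
#' @export
subsample_to_bases <- function(pairs, target_bases, seed) {
  p <- data.table::as.data.table(pairs)
  if (nrow(p) == 0L) stop("empty library")
  stopifnot(target_bases > 0)
  if (sum(as.numeric(p$n_bases)) < target_bases) {
    warning("library smaller than target (",
            sum(as.numeric(p$n_bases)), " < ", target_bases,
            " bases); returning the entire library")
    return(p)
  }
  perm <- subsample_permutation(nrow(p), seed)
  k <- which(cumsum(as.numeric(p$n_bases[perm])) >= target_bases)[1L]
  p[sort(perm[seq_len(k)])]
}

#' Pool libraries with provenance-tagged identifiers
#'
#' Concatenates pair tables, prefixing `pair_id` with the library name
#' (`<library>:<pair_id>`) and recording provenance in `library_id`.
#' Empty libraries are skipped with a warning; identifier collisions after
#' prefixing are an error.
#'
#' @param libraries named list of pair data.tables.
#' @return combined data.table.
#' @export
pool_libraries <- function(libraries) {
  stopifnot(is.list(libraries), !is.null(names(libraries)))
  keep <- vapply(libraries, function(x) nrow(x) > 0L, logical(1))
  if (any(!keep))
    warning("empty library skipped: ",
            paste(names(libraries)[!keep], collapse = ", "))
  libraries <- libraries[keep]
  out <- data.table::rbindlist(lapply(names(libraries), function(nm) {
    x <- data.table::copy(data.table::as.data.table(libraries[[nm]]))
    x[, library_id := nm]
    x[, pair_id := paste0(nm, ":", pair_id)]
    x
  }), fill = TRUE)
  if (anyDuplicated(out$pair_id))
    stop("pair identifier collision after library prefixing")
  out
}

#' Per-step read-accounting report
#'
#' Builds the standard preprocessing accounting table: reads remaining
#' after each step per library, the per-step removal fraction
#' (denominator = reads entering that step), and aggregate rows per
#' platform that sum libraries before dividing.  Removal percentages are
#' also formatted to two decimals.
#'
#' @param counts data.frame with columns `library`, optionally `platform`,
#'   then one column per step of remaining read counts, ordered by
#'   processing step (e.g. `raw`, `filtered`, `mapped`, `deduplicated`).
#' @param steps character vector naming the step columns in order;
#'   defaults to every column after `library`/`platform`.
#' @param categories optional data.frame with `library` and per-category
#'   removed counts at the first filtering step (e.g. `adapter`,
#'   `low_quality`, `ambiguous`); percentages are reported against the
#'   first step's input.
#' @return list of class `StepReport`: `per_library`, `aggregate` and
#'   (optionally) `categories` data.tables.  Each removal column `pct_<s>`
#'   holds the numeric percentage; `fmt_<s>` the two-decimal string.
#' @export
build_step_report <- function(counts, steps = NULL, categories = NULL) {
  ct <- data.table::as.data.table(counts)
  meta <- intersect(c("library", "platform"), names(ct))
  if (!"library" %in% meta) stop("counts must have a 'library' column")
  if (is.null(steps)) steps <- setdiff(names(ct), meta)
  if (length(steps) < 2L) stop("need at least two step columns")
  for (s in steps) ct[[s]] <- as.numeric(ct[[s]])
  dec <- as.matrix(ct[, steps, with = FALSE])
  if (any(dec[, -1L, drop = FALSE] > dec[, -ncol(dec), drop = FALSE]))
    stop("read counts increase across a step")

  add_pct <- function(dt) {
    for (i in seq_along(steps)[-1L]) {
      prev <- dt[[steps[i - 1L]]]; cur <- dt[[steps[i]]]
      pct <- ifelse(prev > 0, 100 * (prev - cur) / prev, 0)
      dt[[paste0("pct_", steps[i])]] <- pct
      dt[[paste0("fmt_", steps[i])]] <- sprintf("%.2f%%", pct)
    }
    dt
  }
  per_library <- add_pct(data.table::copy(ct))
  grp <- if ("platform" %in% meta) "platform" else NULL
  agg <- ct[, lapply(.SD, sum), by = grp, .SDcols = steps]
  if (is.null(grp)) agg[, library := "TOTAL"] else agg[, library := "TOTAL"]
  aggregate <- add_pct(agg)

  out <- list(per_library = per_library, aggregate = aggregate)
  if (!is.null(categories)) {
    cat_dt <- data.table::as.data.table(categories)
    cat_cols <- setdiff(names(cat_dt), c("library", "platform"))
    base <- ct[, c(meta, steps[1L]), with = FALSE]
    cat_dt <- base[cat_dt, on = intersect(meta, names(cat_dt))]
    grp2 <- intersect("platform", names(cat_dt))
    aggc <- cat_dt[, lapply(.SD, sum),
                   by = grp2, .SDcols = c(steps[1L], cat_cols)]
    for (cc in cat_cols) {
      cat_dt[[paste0("pct_", cc)]] <- 100 * cat_dt[[cc]] / cat_dt[[steps[1L]]]
      aggc[[paste0("pct_", cc)]] <- 100 * aggc[[cc]] / aggc[[steps[1L]]]
    }
    out$categories <- cat_dt
    out$categories_aggregate <- aggc
  }
  structure(out, class = "StepReport")
}

#' @export
print.StepReport <- function(x, ...) {
  cat("StepReport:", nrow(x$per_library), "libraries\n")
  print(x$aggregate)
  invisible(x)
}
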