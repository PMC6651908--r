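#' GC-bias analysis parameters
#'
#' @param window window length (bp) along each transcript.
#' @param min_mean_depth minimum average read depth for a transcript to
#'   enter the bias-transcript set.
#' @param min_gap_bases minimum total gap bases for a transcript to enter
#'   the gap-region comparison.
#' @param segment_pct width (percent GC) of the representativeness
#'   histogram segments.
#' @param tpm_threshold minimum TPM (in both libraries) for the
#'   abundance-ratio regression.
#' @return list of class `GcBiasParams`.
#' @export
gc_bias_params <- function(window = 100L, min_mean_depth = 10,
                           min_gap_bases = 10L, segment_pct = 1L,
                           tpm_threshold = 10) {
  stopifnot(window >= 1L, min_mean_depth >= 0, min_gap_bases >= 0L,
            segment_pct >= 1L, tpm_threshold >= 0)
  structure(list(window = as.integer(window),
                 min_mean_depth = min_mean_depth,
                 min_gap_bases = as.integer(min_gap_bases),
                 segment_pct = as.integer(segment_pct),
                 tpm_threshold = tpm_threshold),
            class = "GcBiasParams")
}

#' Gap regions of an annotated transcript
#'
#' A gap is a stretch of the transcript covered by neither scaffold
#' alignments nor any reads.  Transcripts with fewer than `min_gap_bases`
#' total gap bases are excluded from downstream comparisons.
#'
#' @param tx_length transcript length.
#' @param scaffold_intervals data.frame of covered transcript-space
#'   intervals (`start0`, `end0`) from scaffold alignments (may be empty).
#' @param read_intervals data.frame of read-covered transcript-space
#'   intervals (may be empty).
#' @param min_gap_bases inclusion threshold.
#' @return list: `gaps` (data.table `start0`, `end0`), `gap_bases`,
#'   `assembled` (data.table, scaffold-covered union), `included`.
#' @export
gap_regions <- function(tx_length, scaffold_intervals, read_intervals,
                        min_gap_bases = 10L) {
  as_ir <- function(x) {
    x <- data.table::as.data.table(x)
    if (nrow(x) == 0L) IRanges::IRanges() else iranges0(x$start0, x$end0)
  }
  scaf <- IRanges::reduce(as_ir(scaffold_intervals))
  rds <- IRanges::reduce(as_ir(read_intervals))
  covered <- IRanges::reduce(c(scaf, rds))
  full <- IRanges::IRanges(1L, tx_length)
  gaps <- IRanges::setdiff(full, covered)
  gap_bases <- sum(IRanges::width(gaps))
  list(gaps = dt_from_iranges(gaps), gap_bases = gap_bases,
       assembled = dt_from_iranges(scaf),
       included = gap_bases >= min_gap_bases)
}

#' Platform-discordant transcript selection
#'
#' For the gap analysis of platform A, transcripts are chosen when they
#' are complete in no library of platform A but complete in at least one
#' library of the other platform.
#'
#' @param complete_sets named list of complete-transcript id vectors.
#' @param platforms character vector of platform labels along
#'   `complete_sets`.
#' @return named list (one element per platform) of transcript id vectors
#'   failing only on that platform.
#' @export
select_discordant_transcripts <- function(complete_sets, platforms) {
  stopifnot(length(complete_sets) == length(platforms))
  out <- lapply(unique(platforms), function(p) {
    own <- unique(unlist(complete_sets[platforms == p]))
    other <- unique(unlist(complete_sets[platforms != p]))
    sort(setdiff(other, own))
  })
  stats::setNames(out, unique(platforms))
}

#' Length-weighted GC cumulative distributions of region sets
#'
#' Computes the GC content of each region on the reference transcript
#' sequence and returns the empirical CDF over regions weighted by region
#' length.  Regions consisting only of N bases are skipped with a message.
#'
#' @param regions data.frame with `tx_id`, `start0`, `end0` (transcript
#'   space).
#' @param tx_seqs named character vector of transcript sequences.
#' @return data.table `gc`, `cum_fraction`, sorted by `gc` (empty when no
#'   usable regions).
#' @export
gc_cumulants <- function(regions, tx_seqs) {
  rg <- data.table::as.data.table(regions)
  if (nrow(rg) == 0L)
    return(data.table::data.table(gc = numeric(0), cum_fraction = numeric(0)))
  sq <- substring(tx_seqs[rg$tx_id], rg$start0 + 1L, rg$end0)
  gc <- gc_fraction(sq)
  if (anyNA(gc)) {
    message(sum(is.na(gc)), " all-N region(s) skipped")
    rg <- rg[!is.na(gc)]; sq <- sq[!is.na(gc)]; gc <- gc[!is.na(gc)]
  }
  w <- rg$end0 - rg$start0
  o <- order(gc)
  data.table::data.table(gc = gc[o], cum_fraction = cumsum(w[o]) / sum(w))
}

#' Select transcripts for the windowed GC-bias analysis
#'
#' Keeps transcripts with zero genomic overlap with any other annotated
#' transcript (so read depth is unambiguously attributable) and a minimum
#' average raw-position read depth in every supplied dataset.  Also
#' reports the Spearman correlation between the GC-content histograms
#' (1 percent segments) of the selected versus all transcripts, the
#' representativeness check.
#'
#' @param annotation an `AnnotationSet`.
#' @param depth_tracks list (one per dataset) of named per-transcript
#'   depth vectors, e.g. from [transcript_depth()].
#' @param tx_gc named vector of per-transcript GC content.
#' @param params a [gc_bias_params()].
#' @return list: `tx_ids`, `spearman_rho`, `n_selected`.
#' @export
select_bias_transcripts <- function(annotation, depth_tracks, tx_gc,
                                    params = gc_bias_params()) {
  spans <- granges0(annotation$transcripts[, .(seqname, start0, end0)])
  n_ov <- GenomicRanges::countOverlaps(spans, spans, ignore.strand = TRUE)
  nonov <- annotation$transcripts$tx_id[n_ov == 1L]
  deep <- Reduce(intersect, lapply(depth_tracks, function(d) {
    names(d)[vapply(d, mean, numeric(1)) >= params$min_mean_depth]
  }))
  sel <- intersect(nonov, deep)
  if (length(sel) == 0L)
    stop("no transcript passes the overlap/depth selection; ",
         "lower min_mean_depth or provide deeper data")
  brk <- seq(0, 100, by = params$segment_pct)
  hist_of <- function(ids) {
    as.integer(table(cut(100 * tx_gc[ids], breaks = brk,
                         include.lowest = TRUE)))
  }
  all_ids <- annotation$transcripts$tx_id
  rho <- stats::cor(hist_of(sel), hist_of(all_ids), method = "spearman")
  list(tx_ids = sort(sel), spearman_rho = rho, n_selected = length(sel))
}

#' Windowed depth-ratio GC-bias curve
#'
#' Tiles each selected transcript with non-overlapping windows from its 5'
#' end (a trailing partial window is discarded), computes each window's GC
#' content (integer percent bin) and the ratio of window mean depth to the
#' transcript's raw-position mean depth, and averages the ratios per GC
#' bin.  A flat curve at 1 indicates no bias.
#'
#' @param tx_ids transcripts to analyse.
#' @param depth_track named list of per-transcript depth vectors.
#' @param tx_seqs named character vector of transcript sequences.
#' @param params a [gc_bias_params()].
#' @return list of class `GcBiasCurve`: `curve` (data.table `gc_bin`,
#'   `mean_ratio`, `n_windows`), `windows` (per-window table),
#'   `global_mean_ratio`.
#' @export
gc_bias_curve <- function(tx_ids, depth_track, tx_seqs,
                          params = gc_bias_params()) {
  w <- params$window
  rows <- lapply(tx_ids, function(id) {
    d <- depth_track[[id]]
    L <- length(d)
    if (L < w) return(NULL)   # shorter than one window: skipped
    nw <- L %/% w
    td <- mean(d)
    if (td == 0) return(NULL)
    starts <- w * (seq_len(nw) - 1L)
    win_seq <- substring(tx_seqs[[id]], starts + 1L, starts + w)
    win_gc <- gc_fraction(win_seq)
    win_depth <- vapply(seq_len(nw), function(k)
      mean(d[(starts[k] + 1L):(starts[k] + w)]), numeric(1))
    data.table::data.table(tx_id = id, win_start0 = starts,
                           gc_bin = as.integer(round(100 * win_gc)),
                           ratio = win_depth / td)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) message(skipped, " transcript(s) shorter than one window ",
                       "or without reads skipped")
  win <- data.table::rbindlist(rows)
  if (nrow(win) == 0L) stop("no windows to analyse")
  curve <- win[!is.na(gc_bin),
               .(mean_ratio = mean(ratio), n_windows = .N),
               by = gc_bin][order(gc_bin)]
  structure(list(curve = curve, windows = win,
                 global_mean_ratio = win[, mean(ratio)]),
            class = "GcBiasCurve")
}

#' Transcripts-per-million estimates from direct counts
#'
#' `rate_i = count_i / effective_length_i`; `TPM_i = 1e6 rate_i / sum rate`.
#' TPMs sum to one million by construction.
#'
#' @param counts named vector of read (pair) counts per transcript.
#' @param lengths named vector of effective transcript lengths.
#' @return named numeric vector of TPM values.
#' @export
tpm_estimates <- function(counts, lengths) {
  ids <- names(counts)
  stopifnot(!is.null(ids), all(ids %in% names(lengths)))
  if (sum(counts) == 0) stop("zero total count")
  rate <- counts / lengths[ids]
  1e6 * rate / sum(rate)
}

#' Abundance-ratio versus GC regression
#'
#' Includes transcripts with TPM at or above the threshold in both
#' libraries, regresses the base-10 log ratio of library-1 to library-2
#' TPM on GC content (ordinary least squares) and returns the fitted
#' parameters.
#'
#' @param tpm1,tpm2 named TPM vectors over the same transcript universe.
#' @param tx_gc named per-transcript GC content (fraction in 0..1).
#' @param params a [gc_bias_params()] (uses `tpm_threshold`).
#' @return list: `slope`, `intercept`, `slope_se`, `n`,
#'   `included_fraction`.
#' @export
abundance_ratio_regression <- function(tpm1, tpm2, tx_gc,
                                       params = gc_bias_params()) {
  ids <- intersect(names(tpm1), names(tpm2))
  keep <- ids[tpm1[ids] >= params$tpm_threshold &
              tpm2[ids] >= params$tpm_threshold]
  if (length(keep) < 3L)
    stop("fewer than 3 transcripts pass the TPM threshold in both libraries")
  y <- log10(tpm1[keep] / tpm2[keep])
  x <- tx_gc[keep]
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       slope_se = unname(sm[2L, 2L]), n = length(keep),
       included_fraction = length(keep) / length(ids))
}
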