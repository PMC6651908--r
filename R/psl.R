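#' Read BLAT PSL alignments
#'
#' Parses the standard 21-column PSL format (with or without the
#' `psLayout` header).  Block coordinate lists are reconstructed from
#' `blockSizes`/`qStarts`/`tStarts`.  For minus-strand rows, query block
#' starts (which PSL stores in reversed-query coordinates) are normalized
#' to the plus-strand query frame, so downstream code never needs to
#' special-case strand when reasoning about which query bases are aligned.
#'
#' All coordinates are 0-based half-open, matching both PSL and the
#' internal convention.
#'
#' @param path path to a PSL file.
#' @return data.table with one row per alignment: `matches`, `strand`,
#'   `q_name`, `q_size`, `t_name`, `t_size`, `block_count`, list-columns
#'   `block_sizes`, `q_starts` (plus frame), `t_starts` (target order),
#'   and derived `aligned_bases`, `aligned_fraction`.
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  # optional header: psLayout line, column captions, dashes separator
  dash <- grep("^-{5,}", lines)
  if (length(dash)) lines <- lines[-seq_len(dash[1L])]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_psl())
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf != 21L))
    stop("PSL column count mismatch (expected 21) at line ",
         which(nf != 21L)[1L])
  m <- do.call(rbind, fields)
  int_list <- function(col) lapply(strsplit(col, ","), as.integer)
  dt <- data.table::data.table(
    matches = as.integer(m[, 1L]), mismatches = as.integer(m[, 2L]),
    rep_matches = as.integer(m[, 3L]), n_count = as.integer(m[, 4L]),
    strand = m[, 9L], q_name = m[, 10L], q_size = as.integer(m[, 11L]),
    q_start = as.integer(m[, 12L]), q_end = as.integer(m[, 13L]),
    t_name = m[, 14L], t_size = as.integer(m[, 15L]),
    t_start = as.integer(m[, 16L]), t_end = as.integer(m[, 17L]),
    block_count = as.integer(m[, 18L]),
    block_sizes = int_list(m[, 19L]),
    q_starts = int_list(m[, 20L]),
    t_starts = int_list(m[, 21L]))
  if (!all(dt$strand %in% c("+", "-")))
    stop("unsupported PSL strand value (expected '+' or '-')")
  # normalize minus-strand query coordinates to the plus-strand frame
  dt[, q_starts := Map(function(st, qs, sz, qsize) {
    if (st == "-") qsize - qs - sz else qs
  }, strand, q_starts, block_sizes, q_size)]
  bad <- dt[, mapply(function(sz, qs, ts, qsize, tsize) {
    length(sz) != length(qs) || length(sz) != length(ts) ||
      any(qs < 0L) || any(qs + sz > qsize) || any(ts + sz > tsize) ||
      sum(sz) > qsize
  }, block_sizes, q_starts, t_starts, q_size, t_size)]
  if (any(bad))
    stop("PSL block arithmetic inconsistent with qSize/tSize at record ",
         which(bad)[1L])
  dt[, aligned_bases := vapply(block_sizes, sum, integer(1))]
  dt[, aligned_fraction := aligned_bases / q_size]
  dt[]
}

empty_psl <- function() {
  data.table::data.table(
    matches = integer(0), mismatches = integer(0), rep_matches = integer(0),
    n_count = integer(0), strand = character(0), q_name = character(0),
    q_size = integer(0), q_start = integer(0), q_end = integer(0),
    t_name = character(0), t_size = integer(0), t_start = integer(0),
    t_end = integer(0), block_count = integer(0), block_sizes = list(),
    q_starts = list(), t_starts = list(), aligned_bases = integer(0),
    aligned_fraction = numeric(0))
}

#' Write alignments in 21-column PSL format
#'
#' Inverse of [read_psl()]: internal plus-frame query coordinates of
#' minus-strand rows are converted back to PSL's reversed-query frame.
#'
#' @param psl data.table in the [read_psl()] layout.
#' @param path output path.
#' @export
write_psl <- function(psl, path) {
  psl <- data.table::as.data.table(psl)
  rows <- vapply(seq_len(nrow(psl)), function(i) {
    r <- psl[i]
    sz <- r$block_sizes[[1L]]; qs <- r$q_starts[[1L]]; ts <- r$t_starts[[1L]]
    if (r$strand == "-") qs <- r$q_size - qs - sz
    paste(r$matches, r$mismatches %||% 0L, r$rep_matches %||% 0L,
          r$n_count %||% 0L, 0L, 0L, 0L, 0L, r$strand, r$q_name, r$q_size,
          min(psl$q_starts[[i]]), max(psl$q_starts[[i]] + sz),
          r$t_name, r$t_size, min(ts), max(ts + sz), length(sz),
          paste0(paste(sz, collapse = ","), ","),
          paste0(paste(qs, collapse = ","), ","),
          paste0(paste(ts, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

# Explode a PSL table into one row per target block, carrying the matched
# plus-frame query interval.
psl_blocks <- function(psl) {
  if (nrow(psl) == 0L)
    return(data.table::data.table(q_name = character(0),
                                  t_name = character(0),
                                  seqname = character(0),
                                  start0 = integer(0), end0 = integer(0),
                                  q_block_start = integer(0),
                                  q_block_end = integer(0),
                                  aln_id = integer(0)))
  n <- vapply(psl$block_sizes, length, integer(1))
  data.table::data.table(
    aln_id = rep(seq_len(nrow(psl)), n),
    q_name = rep(psl$q_name, n),
    t_name = rep(psl$t_name, n),
    seqname = rep(psl$t_name, n),
    strand = rep(psl$strand, n),
    start0 = unlist(psl$t_starts),
    end0 = unlist(psl$t_starts) + unlist(psl$block_sizes),
    q_block_start = unlist(psl$q_starts),
    q_block_end = unlist(psl$q_starts) + unlist(psl$block_sizes))
}
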