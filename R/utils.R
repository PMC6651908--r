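# Internal helpers shared across modules.
#
# Coordinate convention: all internal intervals are 0-based half-open
# [start0, end0).  Conversion to 1-based closed happens only at the GFF3
# boundary and when talking to IRanges (1-based closed).

# Derive a per-stage seed from the master seed, deterministically and
# stage-distinctly.  Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 1000003L) * 2017L + h) %% 2147483629L
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# IRanges from 0-based half-open columns; empty input allowed.
iranges0 <- function(start0, end0) {
  IRanges::IRanges(start = as.integer(start0) + 1L, end = as.integer(end0))
}

# data.table(start0, end0) from an IRanges.
dt_from_iranges <- function(ir) {
  data.table::data.table(start0 = IRanges::start(ir) - 1L,
                         end0   = IRanges::end(ir))
}

# GRanges from a data.table with seqname/start0/end0 (strand ignored:
# coverage and classification are strand-blind).
granges0 <- function(dt) {
  GenomicRanges::GRanges(seqnames = dt$seqname,
                         ranges = iranges0(dt$start0, dt$end0))
}

# Total unique bases in a set of 0-based half-open intervals (per seqname).
union_size <- function(dt) {
  if (nrow(dt) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(granges0(dt))))
}

# Random DNA string of length n with given GC content.
random_dna <- function(n, gc = 0.42) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# GC fraction of character sequences; N bases excluded from the denominator,
# all-N (or empty) sequences give NA.
gc_fraction <- function(x) {
  xs <- Biostrings::DNAStringSet(x)
  counts <- Biostrings::letterFrequency(xs, c("G", "C", "A", "T"))
  gcn <- counts[, "G"] + counts[, "C"]
  tot <- gcn + counts[, "A"] + counts[, "T"]
  ifelse(tot == 0L, NA_real_, gcn / tot)
}

# Reverse complement of plain character sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Merge overlapping/adjacent 0-based intervals within groups; returns a
# data.table with the grouping columns preserved.
merge_intervals <- function(dt, by = "tx_id") {
  if (nrow(dt) == 0L) return(dt)
  dt <- data.table::as.data.table(dt)
  dt[, {
    ir <- IRanges::reduce(iranges0(start0, end0))
    list(start0 = IRanges::start(ir) - 1L, end0 = IRanges::end(ir))
  }, by = by]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
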