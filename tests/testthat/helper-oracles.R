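# Brute-force oracles and tiny fixture builders, independent of the
# package's interval/scan implementations.

# Boolean-array union size of 0-based half-open blocks over named sequences.
bf_union_size <- function(blocks, seqlens) {
  tot <- 0L
  for (sq in unique(blocks$seqname)) {
    v <- logical(seqlens[[sq]])
    b <- blocks[blocks$seqname == sq, , drop = FALSE]
    for (i in seq_len(nrow(b)))
      if (b$end0[i] > b$start0[i]) v[(b$start0[i] + 1L):b$end0[i]] <- TRUE
    tot <- tot + sum(v)
  }
  tot
}

# Boolean-array intersection size of two block sets.
bf_intersect_size <- function(a, b, seqlens) {
  tot <- 0L
  for (sq in union(a$seqname, b$seqname)) {
    va <- logical(seqlens[[sq]]); vb <- logical(seqlens[[sq]])
    aa <- a[a$seqname == sq, , drop = FALSE]
    bb <- b[b$seqname == sq, , drop = FALSE]
    for (i in seq_len(nrow(aa)))
      if (aa$end0[i] > aa$start0[i]) va[(aa$start0[i] + 1L):aa$end0[i]] <- TRUE
    for (i in seq_len(nrow(bb)))
      if (bb$end0[i] > bb$start0[i]) vb[(bb$start0[i] + 1L):bb$end0[i]] <- TRUE
    tot <- tot + sum(va & vb)
  }
  tot
}

# Exhaustive six-frame ORF scan: for every ATG, walk codon by codon to the
# first stop; returns the longest peptide length (aa, incl. Met).
bf_longest_orf <- function(seq) {
  rc <- function(x) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  best <- 0L
  for (s in c(toupper(seq), rc(toupper(seq)))) {
    n <- nchar(s)
    for (start in seq_len(max(n - 5L, 0L))) {
      if (substring(s, start, start + 2L) != "ATG") next
      p <- start + 3L
      while (p + 2L <= n) {
        cod <- substring(s, p, p + 2L)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, (p - start) %/% 3L)
          break
        }
        p <- p + 3L
      }
    }
  }
  best
}

# Random block set on one sequence for interval oracles.
random_blocks <- function(n, seqlen, seqname = "s1") {
  s <- sample.int(seqlen, n, replace = TRUE) - 1L
  w <- sample.int(max(seqlen %/% 4L, 2L), n, replace = TRUE)
  data.table::data.table(seqname = seqname, start0 = s,
                         end0 = pmin(s + w, seqlen))
}

# One-row PSL table built from explicit blocks (plus-frame query coords).
make_psl <- function(q_name, q_size, t_name, t_size, q_starts, t_starts,
                     sizes, strand = "+") {
  data.table::data.table(
    matches = sum(sizes), mismatches = 0L, rep_matches = 0L, n_count = 0L,
    strand = strand, q_name = q_name, q_size = as.integer(q_size),
    q_start = min(q_starts), q_end = max(q_starts + sizes),
    t_name = t_name, t_size = as.integer(t_size),
    t_start = min(t_starts), t_end = max(t_starts + sizes),
    block_count = length(sizes), block_sizes = list(as.integer(sizes)),
    q_starts = list(as.integer(q_starts)),
    t_starts = list(as.integer(t_starts)),
    aligned_bases = sum(sizes), aligned_fraction = sum(sizes) / q_size)
}

# Small shared simulation, built once per test run.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 12L, n_unannotated = 6L,
                        intron_length = c(1500L, 3000L),
                        unannotated_length = c(400L, 900L),
                        n_pairs = 4000L, seed = 402L)
      g <- simulate_genome_annotation(cfg)
      rs <- simulate_reads(g$genome, g$truth, cfg)
      cache <<- list(cfg = cfg, genome = g$genome,
                     annotation = g$annotation, truth = g$truth, reads = rs)
    }
    cache
  }
})
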