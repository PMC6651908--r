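test_that("gene/exon/intron counting matches the configuration", {
  cfg <- sim_config(n_genes = 10L, exon_count = c(3L, 3L), n_pairs = 100L,
                    seed = 5L)
  g <- simulate_genome_annotation(cfg)
  expect_identical(nrow(g$annotation$transcripts), 10L)
  expect_identical(nrow(g$annotation$exons), 30L)
  expect_identical(nrow(g$annotation$introns), 20L)
})

test_that("same seed gives byte-identical FASTA and GFF3", {
  cfg <- sim_config(n_genes = 6L, n_unannotated = 3L, n_pairs = 100L,
                    seed = 99L)
  g1 <- simulate_genome_annotation(cfg)
  g2 <- simulate_genome_annotation(cfg)
  d <- withr::local_tempdir()
  write_fasta(g1$genome, file.path(d, "a.fa"))
  write_fasta(g2$genome, file.path(d, "b.fa"))
  expect_identical(readLines(file.path(d, "a.fa")),
                   readLines(file.path(d, "b.fa")))
  write_gff3(g1$annotation, file.path(d, "a.gff3"))
  write_gff3(g2$annotation, file.path(d, "b.gff3"))
  expect_identical(readLines(file.path(d, "a.gff3")),
                   readLines(file.path(d, "b.gff3")))
})

test_that("unannotated intronic templates lie inside the intron union", {
  s <- small_sim()
  un <- s$truth$transcripts[annotated == FALSE]
  expect_gt(nrow(un), 0L)
  iu <- s$annotation$intron_union
  for (i in seq_len(nrow(un))) {
    q <- GenomicRanges::GRanges(un$seqname[i],
                                IRanges::IRanges(un$start0[i] + 1L,
                                                 un$end0[i]))
    ov <- GenomicRanges::intersect(q, iu, ignore.strand = TRUE)
    expect_identical(sum(IRanges::width(ov)), un$end0[i] - un$start0[i])
  }
  expect_true(all(un$intronic))
})

test_that("abundances follow the configured exponential law", {
  # many single-exon micro-genes keep the genome small while giving a
  # large abundance sample for the rate check
  cfg <- sim_config(n_genes = 2000L, exon_count = c(1L, 1L),
                    exon_length = c(60L, 60L),
                    intergenic_length = c(10L, 30L),
                    abundance_rate = 2.5, n_pairs = 100L, seed = 31L)
  g <- simulate_genome_annotation(cfg)
  ab <- g$truth$transcripts$abundance
  expect_length(ab, 2000L)
  rate_hat <- 1 / mean(ab)   # exponential MLE
  expect_lt(abs(rate_hat - 2.5) / 2.5, 0.10)
})

test_that("truth TPM is the molecule-space normalization summing to 1e6", {
  s <- small_sim()
  tr <- s$truth$transcripts
  expect_equal(sum(tr$true_tpm), 1e6)
  expect_equal(tr$true_tpm,
               1e6 * tr$abundance / sum(tr$abundance))
})

test_that("reads are error-free copies of their source transcripts", {
  s <- small_sim()
  ts <- transcript_sequences(s$genome, exons = s$truth$exons)
  rd <- s$reads$reads[!is.na(tx_id)]
  rl <- s$reads$read_length
  m1 <- unname(substring(ts[rd$tx_id], rd$frag_start + 1L,
                         rd$frag_start + rl))
  expect_identical(m1, rd$seq1)
  frag_end <- rd$frag_start + rd$frag_len
  m2 <- unname(substring(ts[rd$tx_id], frag_end - rl + 1L, frag_end))
  # mate 2 is reverse-complemented
  expect_identical(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rd$seq2))), m2)
})

test_that("genome placements are consistent with the genome sequence", {
  s <- small_sim()
  rl <- s$reads$read_length
  pl <- s$reads$placements
  rd <- s$reads$reads[pl, on = "pair_id"]
  # single-exon unannotated templates on '+': mate 1 must read straight
  # off the genome at its placement
  un <- s$truth$transcripts[annotated == FALSE, tx_id]
  sub <- rd[tx_id %in% un][1:min(50, sum(rd$tx_id %in% un))]
  got <- vapply(seq_len(nrow(sub)), function(i)
    genome_subseq(s$genome, sub$seqname[i], sub$pos1[i], sub$pos1[i] + rl),
    character(1))
  expect_identical(got, sub$seq1)
})

test_that("injected duplicate rate is recovered by deduplication", {
  cfg <- sim_config(n_genes = 8L, duplicate_rate = 0.4, n_pairs = 5000L,
                    seed = 77L)
  g <- simulate_genome_annotation(cfg)
  rs <- simulate_reads(g$genome, g$truth, cfg)
  kept <- deduplicate(rs$placements)
  removed_frac <- 1 - length(kept) / nrow(rs$placements)
  se <- sqrt(0.4 * 0.6 / 5000)
  expect_lt(abs(removed_frac - 0.4), 5 * se + 0.01)
  expect_equal(sort(kept),
               sort(deduplicate(rs$placements[pair_id %in% kept])))
})

test_that("read-derived TPM converges to truth at depth", {
  cfg <- sim_config(n_genes = 60L, n_pairs = 100000L, seed = 13L)
  g <- simulate_genome_annotation(cfg)
  rs <- simulate_reads(g$genome, g$truth, cfg)
  cnt <- rs$reads[!is.na(tx_id), .N, by = tx_id]
  tlen <- stats::setNames(g$truth$transcripts$length_nt,
                          g$truth$transcripts$tx_id)
  tpm <- tpm_estimates(stats::setNames(cnt$N, cnt$tx_id), tlen)
  truth_tpm <- stats::setNames(g$truth$transcripts$true_tpm,
                               g$truth$transcripts$tx_id)
  # molecule-space sampling is length-blind; compare on the count scale
  rho <- stats::cor(tpm * tlen[names(tpm)], truth_tpm[names(tpm)],
                    method = "spearman")
  expect_gte(rho, 0.99)
})

test_that("scaffolds at fraction 1 reproduce transcripts and exon blocks", {
  s <- small_sim()
  sc <- simulate_scaffolds(s$genome, s$truth)
  ts <- transcript_sequences(s$genome, exons = s$truth$exons)
  tr <- s$truth$transcripts[annotated == TRUE]
  for (tx in tr$tx_id[1:5]) {
    expect_identical(unname(sc$scaffolds[paste0("scaf_", tx)]),
                     unname(ts[tx]))
    aln <- sc$psl[q_name == paste0("scaf_", tx)]
    ex <- s$annotation$exons[tx_id == tx][order(start0)]
    expect_equal(aln$t_starts[[1]], ex$start0)
    expect_equal(aln$t_starts[[1]] + aln$block_sizes[[1]], ex$end0)
    expect_equal(aln$aligned_fraction, 1.0)
  }
})

test_that("fractional scaffolds miss the completeness threshold", {
  s <- small_sim()
  tr <- s$truth$transcripts[annotated == TRUE]
  sc <- simulate_scaffolds(s$genome, s$truth, tx_ids = tr$tx_id,
                           fraction = 0.9)
  tlen <- stats::setNames(tr$length_nt, tr$tx_id)
  comp <- complete_transcripts(
    project_to_transcripts(sc$psl, s$annotation), tlen)
  expect_length(comp, 0L)
})

test_that("chimeric scaffolds never reach the filter on one alignment", {
  s <- small_sim()
  sc <- simulate_scaffolds(s$genome, s$truth, n_chimera = 5L)
  chim <- sc$truth[chimeric == TRUE, unique(scaffold_id)]
  expect_length(chim, 5L)
  expect_true(all(sc$psl[q_name %in% chim, aligned_fraction] < 0.98))
})

test_that("spike-in pairs have no genome placement", {
  cfg <- sim_config(n_genes = 5L, n_pairs = 1000L, spike_in = 0.2,
                    seed = 12L)
  g <- simulate_genome_annotation(cfg)
  rs <- simulate_reads(g$genome, g$truth, cfg)
  expect_identical(nrow(rs$reads), 1000L)
  expect_identical(sum(is.na(rs$reads$tx_id)), 200L)
  expect_identical(nrow(rs$placements), 800L)
})
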