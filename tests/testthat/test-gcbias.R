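test_that("gap regions are the complement of scaffold and read coverage", {
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.table::data.table(start0 = m[, 1], end0 = m[, 2])
  }
  g <- gap_regions(200L, iv(0L, 150L), iv(0L, 160L))
  expect_equal(g$gaps, data.table::data.table(start0 = 160L, end0 = 200L))
  expect_identical(g$gap_bases, 40L)
  expect_true(g$included)
  # reads alone veto gaps
  g2 <- gap_regions(200L, iv(0L, 100L), iv(0L, 200L))
  expect_identical(g2$gap_bases, 0L)
  expect_false(g2$included)
  # 9 gap bases: excluded
  g3 <- gap_regions(200L, iv(0L, 191L), iv(0L, 191L))
  expect_identical(g3$gap_bases, 9L)
  expect_false(g3$included)
  # partition: assembled + gaps + read-only cover the transcript exactly
  g4 <- gap_regions(300L, iv(0L, 120L), iv(100L, 220L))
  covered <- rbind(g4$assembled, iv(100L, 220L), g4$gaps)
  expect_identical(
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(covered$start0 + 1L, covered$end0)))), 300L)
})

test_that("discordant transcripts fail on exactly one platform", {
  sets <- list(a1 = c("t1", "t2"), a2 = c("t2"),
               b1 = c("t1", "t3"), b2 = c("t4"))
  d <- select_discordant_transcripts(sets, c("A", "A", "B", "B"))
  # complete on B but never on A
  expect_identical(d$A, c("t3", "t4"))
  # complete on A but never on B
  expect_identical(d$B, "t2")
  # t1 complete on both platforms appears nowhere; a transcript complete
  # nowhere appears nowhere
  expect_false("t1" %in% unlist(d))
})

test_that("GC cumulants are length-weighted and ordered", {
  seqs <- c(t1 = strrep("AT", 200), t2 = strrep("GC", 200),
            t3 = paste0(strrep("A", 100), strrep("G", 100)))
  rg <- data.table::data.table(tx_id = c("t1", "t2"),
                               start0 = 0L, end0 = 100L)
  cdf <- gc_cumulants(rg, seqs)
  expect_equal(cdf$gc, c(0, 1))
  expect_equal(cdf$cum_fraction, c(0.5, 1))
  # identical region sets give identical CDFs
  expect_identical(gc_cumulants(rg, seqs), gc_cumulants(rg, seqs))
  # all-N regions are skipped
  seqN <- c(n1 = strrep("N", 50), t1 = strrep("AT", 100))
  rgN <- data.table::data.table(tx_id = c("n1", "t1"),
                                start0 = 0L, end0 = 50L)
  expect_message(cdfN <- gc_cumulants(rgN, seqN), "skipped")
  expect_identical(nrow(cdfN), 1L)
})

merge_asm <- function(id, cov, L) {
  ir <- IRanges::reduce(IRanges::IRanges(cov$start0 + 1L, cov$end0))
  data.table::data.table(tx_id = id,
                         start0 = IRanges::start(ir) - 1L,
                         end0 = pmin(IRanges::end(ir), L))
}

test_that("gap CDF shifts right when coverage is GC-biased", {
  w <- function(gc) exp(-6 * pmax(0, gc - 0.5))
  cfg <- sim_config(n_genes = 40L, exon_count = c(1L, 1L),
                    exon_length = c(2100L, 2100L), gc_mean = c(0.3, 0.8),
                    gc_profile = "segmented", gc_segment_length = 700L,
                    fragment_mean = 200, fragment_sd = 20,
                    n_pairs = 6000L, gc_bias = w, seed = 44L)
  g <- simulate_genome_annotation(cfg)
  rs <- simulate_reads(g$genome, g$truth, cfg)
  txseq <- transcript_sequences(g$genome, exons = g$truth$exons)
  tlen <- stats::setNames(g$truth$transcripts$length_nt,
                          g$truth$transcripts$tx_id)
  rl <- rs$read_length
  iv <- rbind(rs$reads[, .(tx_id, start0 = frag_start,
                           end0 = frag_start + rl)],
              rs$reads[, .(tx_id, start0 = frag_start + frag_len - rl,
                           end0 = frag_start + frag_len)])
  gaps <- list(); asm <- list()
  for (id in names(tlen)) {
    gr <- gap_regions(tlen[[id]], iv[0L], iv[tx_id == id])
    if (gr$included) {
      if (nrow(gr$gaps)) gaps[[id]] <- cbind(tx_id = id, gr$gaps)
      cov <- data.table::as.data.table(iv[tx_id == id])
      # "assembled" stand-in: read-covered union
      asm[[id]] <- merge_asm(id, cov, tlen[[id]])
    }
  }
  gap_dt <- data.table::rbindlist(gaps)
  asm_dt <- data.table::rbindlist(asm)
  expect_gt(nrow(gap_dt), 0L)
  cdf_gap <- gc_cumulants(gap_dt, txseq)
  cdf_asm <- gc_cumulants(asm_dt, txseq)
  mean_gc <- function(cdf) {
    wts <- diff(c(0, cdf$cum_fraction))
    sum(cdf$gc * wts)
  }
  expect_gt(mean_gc(cdf_gap), mean_gc(cdf_asm) + 0.05)
})

test_that("bias-transcript selection enforces overlap and depth rules", {
  # two overlapping transcripts plus two isolated ones
  ex <- data.table::data.table(
    tx_id = c("o1", "o2", "i1", "i2"),
    gene_id = c("go1", "go2", "gi1", "gi2"),
    seqname = "c1", strand = "+",
    start0 = c(100L, 300L, 5000L, 9000L),
    end0 = c(600L, 800L, 5400L, 9400L))
  ann <- annotation_set(ex, c(c1 = 20000L))
  mkd <- function(vals) lapply(vals, function(v) rep(v, 400L))
  d1 <- stats::setNames(mkd(c(50, 50, 50, 50)), c("o1", "o2", "i1", "i2"))
  d2 <- stats::setNames(mkd(c(50, 50, 9.9, 50)), c("o1", "o2", "i1", "i2"))
  gcv <- stats::setNames(c(0.4, 0.5, 0.45, 0.6), c("o1", "o2", "i1", "i2"))
  sel <- select_bias_transcripts(ann, list(d1, d2), gcv)
  # overlapping pair excluded; i1 fails the all-dataset depth rule
  expect_identical(sel$tx_ids, "i2")
  # selection equal to the full set gives rho 1
  sel2 <- select_bias_transcripts(ann, list(d1), gcv)
  expect_setequal(sel2$tx_ids, c("i1", "i2"))
  selfcheck <- select_bias_transcripts(
    annotation_set(ex[3:4], c(c1 = 20000L)), list(d1[3:4]), gcv[3:4])
  expect_equal(selfcheck$spearman_rho, 1.0)
  expect_error(select_bias_transcripts(ann, list(stats::setNames(
    mkd(c(1, 1, 1, 1)), names(d1))), gcv), "no transcript")
})

test_that("depth-ratio windows and bins follow the definition", {
  seqs <- c(t1 = strrep("ATGC", 75))   # 300 b, GC 50%
  depth <- list(t1 = c(rep(10, 100), rep(30, 100), rep(20, 100)))
  cur <- gc_bias_curve("t1", depth, seqs)
  expect_identical(cur$curve$gc_bin, 50L)
  expect_equal(sort(cur$windows$ratio), c(0.5, 1.0, 1.5))
  expect_equal(cur$global_mean_ratio, 1.0)
  # uniform depth: flat curve at exactly 1
  unif <- list(t1 = rep(7, 300))
  cur2 <- gc_bias_curve("t1", unif, seqs)
  expect_equal(cur2$curve$mean_ratio, 1.0)
  # trailing partial window discarded; short transcripts skipped
  seqs2 <- c(t1 = strrep("ATGC", 75), t2 = strrep("A", 50))
  depth2 <- list(t1 = rep(5, 300), t2 = rep(5, 50))
  expect_message(cur3 <- gc_bias_curve(c("t1", "t2"), depth2, seqs2),
                 "skipped")
  expect_identical(sum(cur3$curve$n_windows), 3L)
  # weighted mean of bin means equals the global mean ratio
  expect_equal(cur$curve[, sum(mean_ratio * n_windows) / sum(n_windows)],
               cur$global_mean_ratio)
})

test_that("TPM estimates normalize rates to one million", {
  tpm <- tpm_estimates(c(A = 3, B = 1), c(A = 300, B = 100))
  expect_equal(unname(tpm), c(5e5, 5e5))
  expect_equal(sum(tpm), 1e6)
  expect_equal(unname(tpm_estimates(c(X = 7), c(X = 1000))), 1e6)
  # scale invariance
  t1 <- tpm_estimates(c(A = 3, B = 9), c(A = 100, B = 100))
  t2 <- tpm_estimates(c(A = 6, B = 18), c(A = 100, B = 100))
  expect_equal(t1, t2)
  expect_error(tpm_estimates(c(A = 0), c(A = 100)), "zero total")
})

test_that("abundance-ratio regression applies the dual TPM threshold", {
  gcv <- stats::setNames(seq(0.3, 0.7, length.out = 20),
                         sprintf("t%02d", 1:20))
  tpm <- stats::setNames(rep(5e4, 20), names(gcv))
  fit <- abundance_ratio_regression(tpm, tpm, gcv)
  expect_equal(fit$slope, 0)
  expect_equal(fit$intercept, 0)
  expect_identical(fit$n, 20L)
  # a transcript at TPM 9.9 in one library is excluded
  tpm2 <- tpm; tpm2[["t01"]] <- 9.9
  fit2 <- abundance_ratio_regression(tpm, tpm2, gcv)
  expect_identical(fit2$n, 19L)
  expect_equal(fit2$included_fraction, 19 / 20)
  expect_error(abundance_ratio_regression(
    stats::setNames(c(1, 1, 1), c("a", "b", "c")),
    stats::setNames(c(1, 1, 1), c("a", "b", "c")), gcv), "threshold")
})
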