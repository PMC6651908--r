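ann_1tx <- function(tx_len = 500L, exon_start = 1000L) {
  annotation_set(data.table::data.table(
    tx_id = "t1", gene_id = "g1", seqname = "c1", strand = "+",
    start0 = exon_start, end0 = exon_start + tx_len),
    c(c1 = 100000L))
}

test_that("annotation fraction takes the more favorable denominator", {
  ann <- ann_1tx(tx_len = 500L)
  # 1000 b scaffold overlapping 450 exonic bases of a 500 b transcript
  psl <- make_psl("s1", 1000L, "c1", 100000L, 0L, 1000L, 450L)
  fr <- annotation_fraction(psl, ann)
  expect_equal(fr$frac_scaffold, 0.45)
  expect_equal(fr$frac_transcript, 0.90)
  expect_equal(fr$fraction, 0.90)
  expect_identical(fr$best_tx, "t1")
  # scaffold identical to the transcript
  psl2 <- make_psl("s2", 500L, "c1", 100000L, 0L, 1000L, 500L)
  expect_equal(annotation_fraction(psl2, ann)$fraction, 1.0)
  # zero exon overlap
  psl3 <- make_psl("s3", 500L, "c1", 100000L, 0L, 50000L, 500L)
  fr3 <- annotation_fraction(psl3, ann)
  expect_equal(fr3$fraction, 0)
  expect_true(is.na(fr3$best_tx))
})

test_that("annotated calls use a strict greater-than threshold", {
  fr <- data.table::data.table(q_name = "s", fraction = 0.90)
  sw <- classify_annotated(fr, c(0L, 89L, 90L))
  expect_identical(sw$n_annotated, c(1L, 1L, 0L))
  # monotone non-increasing over the full grid for random fractions
  withr::with_seed(4, {
    frr <- data.table::data.table(q_name = sprintf("s%d", 1:50),
                                  fraction = stats::runif(50))
    sww <- classify_annotated(frr, 0:100)
    expect_true(all(diff(sww$n_annotated) <= 0))
    expect_true(all(sww$n_annotated + sww$n_unannotated == 50L))
  })
})

test_that("exon structure counts intron-sized target gaps only", {
  # gap of 100 >= 30 -> 2 exons
  p1 <- make_psl("a", 200L, "c1", 10000L, c(0L, 100L), c(0L, 200L),
                 c(100L, 100L))
  # gap of 10 < 30 -> treated as indel, 1 exon
  p2 <- make_psl("b", 200L, "c1", 10000L, c(0L, 100L), c(0L, 110L),
                 c(100L, 90L))
  # single block
  p3 <- make_psl("c", 100L, "c1", 10000L, 0L, 0L, 100L)
  es <- exon_structure(rbind(p1, p2, p3), 30L)
  expect_identical(es$exon_count, c(2L, 1L, 1L))
  expect_identical(es$single_exon, c(FALSE, TRUE, TRUE))
  # a large target gap with a large query gap is not an intron
  p4 <- make_psl("d", 400L, "c1", 10000L, c(0L, 300L), c(0L, 1000L),
                 c(100L, 100L))
  expect_identical(exon_structure(p4, 30L)$exon_count, 1L)
})

test_that("minus-strand alignments get the same exon structure", {
  ex <- data.table::data.table(
    tx_id = "tm", gene_id = "gm", seqname = "c1", strand = "-",
    start0 = c(100L, 400L), end0 = c(250L, 520L), exon_rank = c(2L, 1L))
  gm_len <- c(c1 = 10000L)
  ann <- annotation_set(ex, gm_len)
  # scaffold = the spliced transcript, aligned on the minus strand:
  # target blocks are the exons; plus-frame query intervals follow
  # transcript coordinates
  psl <- make_psl("sm", 270L, "c1", 10000L, c(120L, 0L), c(100L, 400L),
                  c(150L, 120L), strand = "-")
  es <- exon_structure(psl, 30L)
  expect_identical(es$exon_count, 2L)
  fr <- annotation_fraction(psl, ann)
  expect_equal(fr$fraction, 1.0)
})

test_that("intronic calls use a strict majority of aligned bases", {
  gm_len <- c(c1 = 100000L)
  ann <- annotation_set(data.table::data.table(
    tx_id = "t1", gene_id = "g1", seqname = "c1", strand = "+",
    start0 = c(1000L, 3000L), end0 = c(1500L, 3500L),
    exon_rank = c(1L, 2L)), gm_len)
  # intron is [1500, 3000)
  fully <- make_psl("in", 300L, "c1", 100000L, 0L, 2000L, 300L)
  sixty <- make_psl("mix60", 500L, "c1", 100000L, 0L, 2800L, 500L)
  tie <- make_psl("tie", 400L, "c1", 100000L, 0L, 2800L, 400L)
  res <- classify_intronic(rbind(fully, sixty, tie), ann)
  rec <- res$records[order(q_name)]
  expect_identical(rec[q_name == "in", intronic], TRUE)
  # mix60: [2800,3300) -> 200 intronic of 500? no: [2800,3000)=200 in,
  # [3000,3300)=300 out -> 40% -> not intronic
  expect_identical(rec[q_name == "mix60", intronic], FALSE)
  # tie: [2800,3200): 200 in / 200 out = exactly 0.5 -> non-intronic
  expect_identical(rec[q_name == "tie", intronic], FALSE)
  expect_equal(res$sei, 1 / 3)
})

test_that("ORF scan honors ATG..stop geometry across six frames", {
  withr::with_seed(8, {
    aa_codons <- c("GCT", "GAA", "TTC", "GGA", "AAA", "CTG", "CCG", "TAC")
    orf100 <- paste0("ATG", paste(sample(aa_codons, 99, replace = TRUE),
                                  collapse = ""), "TAA")
    res <- find_orfs(c(x = orf100), min_aa = 100L)
    expect_identical(res$longest_orf_aa, 100L)
    expect_true(res$has_orf)
    # same ORF on the reverse strand
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(orf100)))
    expect_identical(find_orfs(c(y = rc), 100L)$longest_orf_aa, 100L)
    # 99 aa misses the flag
    orf99 <- paste0("ATG", paste(sample(aa_codons, 98, replace = TRUE),
                                 collapse = ""), "TAA")
    expect_false(find_orfs(c(z = orf99), 100L)$has_orf)
    # no ATG, and ATG without stop
    expect_identical(find_orfs(c(a = strrep("GCT", 120)), 100L)$has_orf,
                     FALSE)
    no_stop <- paste0("ATG", strrep("GCT", 120))
    expect_false(find_orfs(c(b = no_stop), 100L)$has_orf)
  })
})

test_that("short scaffolds are excluded from ORF denominators", {
  s <- small_sim()
  sc <- simulate_scaffolds(s$genome, s$truth)
  flt <- filter_alignments(sc$psl)
  short_id <- names(sc$scaffolds)[nchar(sc$scaffolds) < 300]
  cls <- classify_scaffolds(flt$alignments, s$annotation,
                            scaffold_seqs = sc$scaffolds)
  if (length(short_id)) {
    counted <- cls$records[scaffold_len >= 300, q_name]
    expect_false(any(short_id %in% counted))
  }
  expect_true(all(c("orf_annotated", "orf_unannotated") %in%
                    names(cls$summary)))
  expect_identical(cls$summary$n_annotated + cls$summary$n_unannotated,
                   nrow(cls$records))
})

test_that("intron length summary reports tail fractions", {
  gm_len <- c(c1 = 100000L)
  ann <- annotation_set(data.table::data.table(
    tx_id = c("t1", "t1", "t2", "t2"), gene_id = c("g1", "g1", "g2", "g2"),
    seqname = "c1", strand = "+",
    start0 = c(0L, 200L, 10000L, 12100L),
    end0 = c(100L, 300L, 10100L, 12200L),
    exon_rank = c(1L, 2L, 1L, 2L)), gm_len)
  # introns: 100 b and 2000 b
  sm <- intron_length_summary(ann)
  expect_identical(sm$n_introns, 2L)
  expect_equal(sm$frac_ge_1kb, 0.5)
  expect_equal(sm$frac_ge_10kb, 0)
  expect_identical(sum(sm$histogram$n), sm$n_introns)
  # single-exon-only annotation
  ann2 <- ann_1tx()
  sm2 <- intron_length_summary(ann2)
  expect_identical(sm2$n_introns, 0L)
  expect_identical(nrow(sm2$histogram), 0L)
})
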