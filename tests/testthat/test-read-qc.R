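mk_pair <- function(id, s1, q1, s2 = strrep("A", 100),
                    q2 = rep(30L, 100)) {
  data.table::data.table(pair_id = id, seq1 = s1, seq2 = s2,
                         qual1 = list(as.integer(q1)),
                         qual2 = list(as.integer(q2)))
}

test_that("quality-rule boundaries are strict inequalities", {
  t <- qc_thresholds(adapters = "AGATCGGAAGAG")
  # 11/100 bases below PHRED 10 -> drop (more than 10%)
  p1 <- mk_pair("a", strrep("A", 100), c(rep(9L, 11), rep(30L, 89)))
  expect_identical(as.character(filter_read_pairs(p1, t)$verdict),
                   "drop:low_quality")
  # exactly 10/100 low-quality and exactly 1/100 N -> keep
  p2 <- mk_pair("b", paste0(strrep("A", 99), "N"),
                c(rep(9L, 10), rep(30L, 90)))
  expect_identical(as.character(filter_read_pairs(p2, t)$verdict), "keep")
  # 2/100 N -> drop (more than 1%)
  p3 <- mk_pair("c", paste0(strrep("A", 98), "NN"), rep(30L, 100))
  expect_identical(as.character(filter_read_pairs(p3, t)$verdict),
                   "drop:ambiguous")
})

test_that("anchored adapter matching fires at half-adapter with 1 mismatch", {
  t <- qc_thresholds(adapters = "AGATCGGAAGAG")   # 12-base adapter
  # exact 6-base adapter prefix at the 3' end (>= 50%)
  p <- mk_pair("a", paste0(strrep("T", 94), "AGATCG"), rep(30L, 100))
  expect_identical(as.character(filter_read_pairs(p, t)$verdict),
                   "drop:adapter")
  # 7-base match carrying one mismatch still fires
  p2 <- mk_pair("b", paste0(strrep("T", 93), "AGATCGT"), rep(30L, 100))
  expect_identical(as.character(filter_read_pairs(p2, t)$verdict),
                   "drop:adapter")
  # 5-base prefix (< 50% of adapter) does not
  p3 <- mk_pair("c", paste0(strrep("T", 95), "AGATC"), rep(30L, 100))
  expect_identical(as.character(filter_read_pairs(p3, t)$verdict), "keep")
  # adapter match must be anchored at the 3' end
  p4 <- mk_pair("d", paste0(strrep("T", 40), "AGATCGGAAGAG",
                            strrep("T", 48)), rep(30L, 100))
  expect_identical(as.character(filter_read_pairs(p4, t)$verdict), "keep")
})

test_that("either mate trips the pair and categories follow rule order", {
  t <- qc_thresholds(adapters = "AGATCGGAAGAG")
  # mate 2 bad -> pair dropped
  p <- mk_pair("a", strrep("A", 100), rep(30L, 100),
               s2 = strrep("N", 100), q2 = rep(30L, 100))
  expect_identical(as.character(filter_read_pairs(p, t)$verdict),
                   "drop:ambiguous")
  # adapter on mate 1 + low quality on mate 2 -> adapter wins
  p2 <- mk_pair("b", paste0(strrep("T", 88), "AGATCGGAAGAG"), rep(30L, 100),
                s2 = strrep("A", 100), q2 = rep(2L, 100))
  expect_identical(as.character(filter_read_pairs(p2, t)$verdict),
                   "drop:adapter")
  expect_error(filter_read_pairs(mk_pair("c", "", integer(0)), t), "empty")
})

test_that("clean-pair filter demands same sequence, convergence and span", {
  pl <- data.table::data.table(
    pair_id = c("ok", "diffseq", "samestrand", "farapart", "divergent"),
    seqname = c("c1", "c1", "c1", "c1", "c1"),
    seqname2 = c("c1", "c2", "c1", "c1", "c1"),
    pos1 = c(100L, 100L, 100L, 100L, 5000L),
    pos2 = c(400L, 400L, 400L, 99999L, 100L),
    strand1 = c("+", "+", "+", "+", "+"),
    strand2 = c("-", "-", "+", "-", "-"))
  expect_identical(clean_pair_filter(pl, max_span = 10000L), "ok")
  # unpaired records are excluded with a message
  pl2 <- rbind(pl, data.table::data.table(
    pair_id = "orphan", seqname = "c1", seqname2 = "c1", pos1 = 5L,
    pos2 = NA_integer_, strand1 = "+", strand2 = NA_character_))
  expect_message(kept <- clean_pair_filter(pl2), "unpaired")
  expect_identical(kept, "ok")
})

test_that("deduplication collapses coordinate copies to the smallest id", {
  pl <- data.table::data.table(
    pair_id = c("p3", "p1", "p2", "q1"),
    seqname = "c1", pos1 = c(10L, 10L, 10L, 99L), strand1 = "+",
    pos2 = c(200L, 200L, 200L, 300L), strand2 = "-")
  kept <- deduplicate(pl)
  expect_setequal(kept, c("p1", "q1"))
  expect_identical(deduplicate(pl[pair_id %in% kept]), sort(kept))
  # all-unique input passes through
  uq <- data.table::data.table(pair_id = c("a", "b"), seqname = "c1",
                               pos1 = c(1L, 2L), strand1 = "+",
                               pos2 = c(5L, 6L), strand2 = "-")
  expect_setequal(deduplicate(uq), c("a", "b"))
})

test_that("base-target subsampling includes the crossing pair and nests", {
  p <- data.table::data.table(pair_id = sprintf("p%02d", 1:10),
                              n_bases = rep(200L, 10))
  sub <- subsample_to_bases(p, 1000L, seed = 3L)
  expect_identical(nrow(sub), 5L)
  expect_warning(all10 <- subsample_to_bases(p, 99999L, seed = 3L),
                 "entire library")
  expect_identical(nrow(all10), 10L)
  # truncating one permutation nests subsets
  s2 <- subsample_to_bases(p, 400L, seed = 8L)
  s4 <- subsample_to_bases(p, 800L, seed = 8L)
  expect_true(all(s2$pair_id %in% s4$pair_id))
  expect_lt(nrow(s2), nrow(s4))
})

test_that("subsampling is uniform over pairs", {
  p <- data.table::data.table(pair_id = sprintf("p%03d", 1:100),
                              n_bases = rep(100L, 100))
  hits <- integer(100)
  for (r in 1:1000) {
    sub <- subsample_to_bases(p, 5000L, seed = r)
    hits[match(sub$pair_id, p$pair_id)] <- hits[match(sub$pair_id,
                                                      p$pair_id)] + 1L
  }
  freq <- hits / 1000
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_true(all(abs(freq - 0.5) <= 5 * se))
})

test_that("library pooling tags provenance and respects sizes", {
  mk <- function(n) data.table::data.table(pair_id = sprintf("p%d", seq_len(n)),
                                           n_bases = 200L)
  libs <- list(A = mk(30), B = mk(30), C = mk(30))
  pooled <- pool_libraries(libs)
  expect_identical(nrow(pooled), 90L)
  expect_setequal(unique(pooled$library_id), c("A", "B", "C"))
  expect_warning(pool_libraries(c(libs, list(D = mk(0)))), "empty library")
  # proportional sampling from the pool within multinomial error
  sub <- subsample_to_bases(pooled, 30 * 200L, seed = 4L)
  counts <- table(sub$library_id)
  expect_true(all(abs(counts - 10) <= 5 * sqrt(30 * (1 / 3) * (2 / 3))))
})

test_that("step report reproduces removal-percentage arithmetic", {
  ct <- data.table::data.table(library = c("L1", "L2"),
                               raw = c(1000, 2000),
                               filtered = c(900, 1800),
                               mapped = c(900, 1800))
  rep <- build_step_report(ct)
  expect_equal(rep$per_library$pct_filtered, c(10, 10))
  expect_identical(rep$per_library$fmt_mapped, c("0.00%", "0.00%"))
  expect_equal(rep$aggregate$pct_filtered, 10)
  expect_error(build_step_report(data.table::data.table(
    library = "L1", raw = 100, filtered = 150)), "increase")
})

test_that("filter categories account for every removed pair", {
  t <- qc_thresholds(adapters = "AGATCGGAAGAG")
  withr::with_seed(21, {
    base <- function() paste(sample(c("A", "C", "G", "T"), 100,
                                    replace = TRUE), collapse = "")
    n <- 120
    rows <- lapply(seq_len(n), function(i) {
      kind <- sample(c("ok", "adapter", "lowq", "amb"), 1)
      s1 <- base(); q1 <- rep(30L, 100)
      if (kind == "adapter") s1 <- paste0(substr(s1, 1, 88), "AGATCGGAAGAG")
      if (kind == "lowq") q1 <- c(rep(5L, 20), rep(30L, 80))
      if (kind == "amb") s1 <- paste0(substr(s1, 1, 95), "NNNNN")
      mk_pair(sprintf("p%03d", i), s1, q1, s2 = base())
    })
    pairs <- data.table::rbindlist(rows)
    v <- filter_read_pairs(pairs, t)
    tab <- table(v$verdict)
    removed <- sum(tab[c("drop:adapter", "drop:low_quality",
                         "drop:ambiguous")])
    expect_identical(as.integer(nrow(pairs) - tab[["keep"]]),
                     as.integer(removed))
  })
})
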