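# Published per-library read-accounting counts for the Universal Human
# Reference RNA (UHRR) platform comparison: nine BGISEQ-500 (DNBseq) runs
# and five HiSeq 2000 runs.  These serve as worked-example inputs for
# build_step_report(); counts are read pairs ("spots").

#' UHRR platform-comparison read counts per preprocessing step
#'
#' Reads remaining per library after each preprocessing step (raw input,
#' quality filtering, genome alignment, PCR deduplication) for the public
#' UHRR DNBseq/HiSeq sequencing runs.
#'
#' @return data.table with `platform`, `library`, `raw`, `filtered`,
#'   `mapped`, `deduplicated`.
#' @seealso [build_step_report()]
#' @export
uhrr_step_counts <- function() {
  data.table::data.table(
    platform = rep(c("DNBseq", "HiSeq"), c(9L, 5L)),
    library = c("ERR1831362", "ERR1831363", "ERR1831364", "ERR1831365",
                "ERR1831366", "ERR1831367", "ERR1831368", "ERR1831369",
                "ERR1831370", "SRR1261168", "SRR1261170", "SRR950078",
                "SRR950080", "SRR950084"),
    raw = c(48148821, 29782959, 54940056, 36073210, 43664065, 55025946,
            53296161, 65455754, 29774053, 134921154, 72897482, 100387010,
            91781477, 125083194),
    filtered = c(45828900, 28352783, 52466727, 34329221, 41782043, 52410892,
                 50698009, 62428710, 28307062, 104132308, 33367214, 77761236,
                 69875633, 93367543),
    mapped = c(44015469, 27237354, 50421993, 32932438, 40108615, 50302197,
               48688107, 59984288, 27164676, 101903998, 32597422, 73979293,
               66896955, 89192069),
    deduplicated = c(32497907, 21102998, 36693200, 24745818, 29250048,
                     36153502, 34475744, 41622545, 20606457, 70430950,
                     27498074, 50505406, 49310706, 61653799))
}

#' UHRR per-category filtered read counts
#'
#' Reads removed by the quality filter per category (adapter
#' contamination, low-quality bases, ambiguous Ns) for the same libraries
#' as [uhrr_step_counts()].
#'
#' @return data.table with `platform`, `library`, `adapter`,
#'   `low_quality`, `ambiguous`.
#' @export
uhrr_filter_categories <- function() {
  data.table::data.table(
    platform = rep(c("DNBseq", "HiSeq"), c(9L, 5L)),
    library = c("ERR1831362", "ERR1831363", "ERR1831364", "ERR1831365",
                "ERR1831366", "ERR1831367", "ERR1831368", "ERR1831369",
                "ERR1831370", "SRR1261168", "SRR1261170", "SRR950078",
                "SRR950080", "SRR950084"),
    adapter = c(125926, 79533, 127069, 103994, 110324, 132461, 133444,
                152027, 83674, 3497, 509, 1313463, 2022559, 4443842),
    low_quality = c(1424492, 871008, 1476496, 1051568, 1060462, 1581470,
                    1588843, 1825708, 898776, 30319019, 33381937, 20004668,
                    18689016, 25596160),
    ambiguous = c(769503, 479635, 869764, 588427, 711236, 901123, 875865,
                  1049309, 484541, 466900, 6147822, 1307643, 1194269,
                  1675649))
}
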