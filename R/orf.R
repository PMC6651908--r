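#' Six-frame open reading frame scan
#'
#' Scans all six reading frames of each sequence for ORFs defined as an
#' ATG start codon followed in frame by a stop codon (TAA/TAG/TGA).  ORF
#' length is counted in amino acids, including the initial methionine and
#' excluding the stop.  Codons containing N never match start or stop.
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param min_aa minimum ORF length (amino acids) for the flag.
#' @param mode `"atg_to_stop"` (default) or `"stop_to_stop"`, which counts
#'   the longest open stretch between in-frame stops regardless of ATG.
#' @return data.table: `id`, `longest_orf_aa` (0 when none), `has_orf`.
#' @export
find_orfs <- function(seqs, min_aa = 100L,
                      mode = c("atg_to_stop", "stop_to_stop")) {
  mode <- match.arg(mode)
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  longest <- vapply(seqs, .longest_orf, integer(1), mode = mode)
  data.table::data.table(id = ids, longest_orf_aa = longest,
                         has_orf = longest >= min_aa)
}

.longest_orf <- function(seq, mode = "atg_to_stop") {
  seq <- toupper(seq)
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    n <- nchar(s)
    for (off in 0:2) {
      n_cod <- (n - off) %/% 3L
      if (n_cod < 2L) next
      starts <- off + 3L * (seq_len(n_cod) - 1L) + 1L
      codons <- substring(s, starts, starts + 2L)
      stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))
      if (mode == "atg_to_stop") {
        atg_idx <- which(codons == "ATG")
        if (length(atg_idx) == 0L || length(stop_idx) == 0L) next
        # first in-frame stop strictly after each ATG
        nxt <- stop_idx[findInterval(atg_idx, stop_idx) + 1L]
        len <- nxt - atg_idx           # aa incl. Met, excl. stop
        len <- len[!is.na(len)]
        if (length(len)) best <- max(best, as.integer(len))
      } else {
        bounds <- c(0L, stop_idx, n_cod + 1L)
        open <- diff(bounds) - 1L
        # interior stretches only need a closing stop; require one
        if (length(stop_idx))
          best <- max(best, as.integer(open[-length(open)]))
      }
    }
  }
  best
}
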