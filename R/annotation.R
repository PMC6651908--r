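#' Annotation set
#'
#' Gene/transcript/exon interval model with derived interval tracks: the
#' global exon union ("exome"), per-transcript introns and the global
#' intron union, and the intergenic union (complement of gene spans).
#' All internal coordinates are 0-based half-open; conversion to GFF3's
#' 1-based closed convention happens only in [read_gff3()]/[write_gff3()].
#'
#' @param exons data.frame/data.table with columns `tx_id`, `gene_id`,
#'   `seqname`, `strand` ("+"/"-"), `start0`, `end0`.  Exons of one
#'   transcript must be non-overlapping.
#' @param seqlengths named integer vector of sequence lengths (e.g.
#'   `GenomeModel$lengths`).
#' @return An object of class `AnnotationSet` with elements `genes`,
#'   `transcripts`, `exons`, `introns` (data.tables), `exon_union`,
#'   `intron_union`, `intergenic_union` (GRanges), `exome_size` and
#'   `seqlengths`.
#' @export
annotation_set <- function(exons, seqlengths) {
  ex <- data.table::as.data.table(exons)
  req <- c("tx_id", "seqname", "strand", "start0", "end0")
  if (!all(req %in% names(ex)))
    stop("exon table must have columns: ", paste(req, collapse = ", "))
  if (!"gene_id" %in% names(ex)) ex[, gene_id := tx_id]
  unknown <- setdiff(unique(ex$seqname), names(seqlengths))
  if (length(unknown))
    stop("feature(s) on unknown sequence(s): ", paste(unknown, collapse = ", "))
  if (any(ex$start0 < 0L) ||
      any(ex$end0 > seqlengths[ex$seqname]) || any(ex$end0 <= ex$start0))
    stop("exon interval outside its sequence (or empty)")

  # transcription-order rank: 5'-most exon first
  data.table::setorder(ex, tx_id, start0)
  ex[, exon_rank := ifelse(strand == "-", rev(seq_len(.N)), seq_len(.N)),
     by = tx_id]
  ov <- ex[, any(start0[-1L] < end0[-.N]), by = tx_id]
  if (any(ov$V1))
    stop("overlapping exons within transcript(s): ",
         paste(head(ov$tx_id[ov$V1], 5), collapse = ", "))
  # spliced-coordinate offset of each exon (0-based along the transcript)
  data.table::setorder(ex, tx_id, exon_rank)
  ex[, width0 := end0 - start0]
  ex[, cum_before := cumsum(width0) - width0, by = tx_id]

  tx <- ex[, .(gene_id = gene_id[1L], seqname = seqname[1L],
               strand = strand[1L], start0 = min(start0), end0 = max(end0),
               n_exons = .N, length_nt = sum(width0)), by = tx_id]
  genes <- tx[, .(seqname = seqname[1L], strand = strand[1L],
                  start0 = min(start0), end0 = max(end0)), by = gene_id]

  # per-transcript introns: genome gaps between consecutive exons
  exg <- data.table::copy(ex)[order(tx_id, start0)]
  introns <- exg[, if (.N > 1L)
    list(seqname = seqname[1L], strand = strand[1L],
         start0 = end0[-.N], end0 = start0[-1L]), by = tx_id]
  if (nrow(introns) == 0L)
    introns <- data.table::data.table(tx_id = character(0),
                                      seqname = character(0),
                                      strand = character(0),
                                      start0 = integer(0), end0 = integer(0))

  exon_union <- IRanges::reduce(granges0(ex))
  intron_union <- if (nrow(introns)) IRanges::reduce(granges0(introns))
                  else GenomicRanges::GRanges()
  gene_gr <- IRanges::reduce(granges0(genes[, .(seqname, start0, end0)]))
  all_gr <- GenomicRanges::GRanges(
    seqnames = names(seqlengths),
    ranges = IRanges::IRanges(1L, unname(as.integer(seqlengths))))
  intergenic_union <- GenomicRanges::setdiff(all_gr, gene_gr,
                                             ignore.strand = TRUE)

  structure(list(genes = genes, transcripts = tx, exons = ex,
                 introns = introns, exon_union = exon_union,
                 intron_union = intron_union,
                 intergenic_union = intergenic_union,
                 exome_size = sum(IRanges::width(exon_union)),
                 seqlengths = seqlengths),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons; exome",
      format(x$exome_size, big.mark = ","), "bp\n")
  invisible(x)
}

#' Read a GFF3 annotation
#'
#' Expects gene/mRNA (or transcript)/exon features linked through `Parent`
#' attributes.  GFF3 1-based closed coordinates are converted to the
#' internal 0-based half-open convention; exon/intron/intergenic unions are
#' derived on load.
#'
#' @param path path to a GFF3 file.
#' @param genome a [genome_model()] supplying the sequence-name space and
#'   lengths; mismatching names are an error.
#' @return An [annotation_set()].
#' @export
read_gff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript")
  is_ex <- type == "exon"
  if (!any(is_ex)) stop("no exon features in ", path)
  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1L]] else NA_character_, character(1))
  tx_gr <- gr[is_tx]
  tx_ids <- tx_gr$ID
  tx_parent <- first_parent(tx_gr$Parent)
  ex_gr <- gr[is_ex]
  ex_parent <- first_parent(ex_gr$Parent)
  if (anyNA(ex_parent)) stop("exon feature without Parent in ", path)

  ex <- data.table::data.table(
    tx_id = ex_parent,
    seqname = as.character(GenomicRanges::seqnames(ex_gr)),
    strand = as.character(BiocGenerics::strand(ex_gr)),
    start0 = BiocGenerics::start(ex_gr) - 1L,
    end0 = BiocGenerics::end(ex_gr))
  ex[strand == "*", strand := "+"]

  if (length(tx_ids)) {
    gene_of <- stats::setNames(ifelse(is.na(tx_parent), tx_ids, tx_parent),
                               tx_ids)
    ex[, gene_id := gene_of[tx_id]]
    ex[is.na(gene_id), gene_id := tx_id]
    # exon must lie within its parent transcript's span
    span <- data.table::data.table(
      tx_id = tx_ids,
      t_start0 = BiocGenerics::start(tx_gr) - 1L,
      t_end0 = BiocGenerics::end(tx_gr))
    chk <- span[ex, on = "tx_id"]
    bad <- chk[!is.na(t_start0) & (start0 < t_start0 | end0 > t_end0)]
    if (nrow(bad))
      stop("exon outside parent transcript span: ",
           paste(unique(bad$tx_id), collapse = ", "))
  }
  annotation_set(ex, genome$lengths)
}

#' Write an AnnotationSet as GFF3
#'
#' Deterministic plain writer (gene, mRNA and exon features with `Parent`
#' links), the inverse of [read_gff3()] up to normalization.
#'
#' @param annotation an `AnnotationSet`.
#' @param path output path.
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  tx <- annotation$transcripts
  ex <- annotation$exons[order(tx_id, exon_rank)]
  lines <- c("##gff-version 3",
    sprintf("%s\ttxasmeval\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$seqname, g$start0 + 1L, g$end0, g$strand, g$gene_id),
    sprintf("%s\ttxasmeval\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            tx$seqname, tx$start0 + 1L, tx$end0, tx$strand, tx$tx_id,
            tx$gene_id),
    sprintf("%s\ttxasmeval\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
            ex$seqname, ex$start0 + 1L, ex$end0, ex$strand, ex$tx_id,
            ex$exon_rank, ex$tx_id))
  writeLines(lines, path)
  invisible(path)
}

#' Spliced transcript sequences
#'
#' Concatenates exon sequences in transcription order; minus-strand
#' transcripts are reverse-complemented so the result reads 5' to 3'.
#'
#' @param genome a `GenomeModel`.
#' @param exons exon table (`AnnotationSet$exons` layout); defaults taken
#'   from `annotation`.
#' @param tx_ids transcripts to extract (default: all).
#' @param annotation an `AnnotationSet` (alternative to `exons`).
#' @return Named character vector of spliced sequences.
#' @export
transcript_sequences <- function(genome, annotation = NULL, exons = NULL,
                                 tx_ids = NULL) {
  ex <- data.table::as.data.table(exons %||% annotation$exons)
  if (!is.null(tx_ids)) ex <- ex[tx_id %in% tx_ids]
  ex <- ex[order(tx_id, exon_rank)]
  piece <- substring(genome$sequences[ex$seqname], ex$start0 + 1L, ex$end0)
  piece <- ifelse(ex$strand == "-", revcomp(piece), piece)
  out <- vapply(split(piece, ex$tx_id), paste, character(1), collapse = "")
  out[unique(ex$tx_id)]
}

# --- transcript <-> genome coordinate projection --------------------------

# Ensure an exon table has width0/cum_before spliced offsets.
.with_offsets <- function(ex) {
  ex <- data.table::as.data.table(ex)
  if (!"width0" %in% names(ex)) ex[, width0 := end0 - start0]
  if (!"cum_before" %in% names(ex)) {
    data.table::setorder(ex, tx_id, exon_rank)
    ex[, cum_before := cumsum(width0) - width0, by = tx_id]
  }
  ex
}

#' Map transcript-space intervals to genome blocks
#'
#' Projects 0-based half-open intervals in spliced-transcript coordinates
#' through the exon structure onto the genome.  An interval spanning splice
#' junctions yields one block per touched exon.
#'
#' @param exons exon table with `tx_id`, `seqname`, `strand`, `start0`,
#'   `end0`, `exon_rank`.
#' @param intervals data.frame with `tx_id`, `start0`, `end0` (transcript
#'   space) plus any carry-through columns (e.g. an interval id).
#' @return data.table with the carry-through columns and genome-space
#'   `seqname`, `strand`, `start0`, `end0`, plus `t_start0`/`t_end0`, the
#'   transcript-space sub-interval each block covers.
#' @export
tx_to_genome_blocks <- function(exons, intervals) {
  ex <- .with_offsets(exons)
  iv <- data.table::as.data.table(intervals)
  data.table::setnames(iv, c("start0", "end0"), c("iv_start", "iv_end"))
  j <- ex[iv, on = "tx_id", allow.cartesian = TRUE]
  j <- j[iv_start < cum_before + width0 & iv_end > cum_before]
  j[, `:=`(t_start0 = pmax(iv_start, cum_before),
           t_end0 = pmin(iv_end, cum_before + width0))]
  j[, `:=`(g_start0 = ifelse(strand == "+",
                             start0 + (t_start0 - cum_before),
                             end0 - (t_end0 - cum_before)),
           g_end0 = ifelse(strand == "+",
                           start0 + (t_end0 - cum_before),
                           end0 - (t_start0 - cum_before)))]
  drop <- c("start0", "end0", "exon_rank", "width0", "cum_before",
            "iv_start", "iv_end", "gene_id")
  j[, (intersect(drop, names(j))) := NULL]
  data.table::setnames(j, c("g_start0", "g_end0"), c("start0", "end0"))
  j[]
}

#' Project genome-space blocks onto transcript coordinates
#'
#' The inverse of [tx_to_genome_blocks()]: intersects genome intervals with
#' each transcript's exons and reports the covered spliced-transcript
#' sub-intervals.  Used to evaluate scaffold alignments in transcript space.
#'
#' @param exons exon table (`AnnotationSet$exons` layout).
#' @param blocks data.frame with `seqname`, `start0`, `end0` plus any
#'   carry-through columns.
#' @return data.table with carry-through columns, `tx_id`, and
#'   transcript-space `t_start0`/`t_end0`.
#' @export
genome_blocks_to_tx <- function(exons, blocks) {
  ex <- .with_offsets(exons)
  bl <- data.table::as.data.table(blocks)
  data.table::setnames(bl, c("start0", "end0"), c("b_start", "b_end"))
  if ("strand" %in% names(bl)) bl[, strand := NULL]
  j <- ex[bl, on = "seqname", allow.cartesian = TRUE, nomatch = NULL]
  j <- j[b_start < end0 & b_end > start0]
  if (nrow(j) == 0L) {
    j[, `:=`(t_start0 = integer(0), t_end0 = integer(0))]
  } else {
    j[, `:=`(o_start = pmax(b_start, start0), o_end = pmin(b_end, end0))]
    j[, `:=`(t_start0 = ifelse(strand == "+",
                               cum_before + (o_start - start0),
                               cum_before + (end0 - o_end)),
             t_end0 = ifelse(strand == "+",
                             cum_before + (o_end - start0),
                             cum_before + (end0 - o_start)))]
  }
  drop <- c("start0", "end0", "exon_rank", "width0", "cum_before",
            "gene_id", "strand", "b_start", "b_end", "o_start", "o_end")
  j[, (intersect(drop, names(j))) := NULL]
  j[]
}

#' Intron length summary
#'
#' Histogram of intron lengths plus the fraction of introns at least 1 kb
#' and 10 kb long, supporting cross-species interpretation of coverage
#' curves (genomes rich in long introns accrue far more genomic than exomic
#' sequence).
#'
#' @param annotation an `AnnotationSet`.
#' @param breaks histogram bin boundaries (bp).
#' @return list with `histogram` (data.table `bin`, `n`), `n_introns`,
#'   `frac_ge_1kb`, `frac_ge_10kb`.
#' @export
intron_length_summary <- function(annotation,
                                  breaks = c(0, 100, 500, 1000, 5000, 1e4,
                                             1e5, 1e6, Inf)) {
  len <- annotation$introns[, end0 - start0]
  if (length(len) == 0L) {
    return(list(histogram = data.table::data.table(bin = character(0),
                                                   n = integer(0)),
                n_introns = 0L, frac_ge_1kb = NA_real_,
                frac_ge_10kb = NA_real_))
  }
  cuts <- cut(len, breaks = breaks, right = FALSE, dig.lab = 8)
  list(histogram = data.table::data.table(bin = levels(cuts),
                                          n = as.integer(table(cuts))),
       n_introns = length(len),
       frac_ge_1kb = mean(len >= 1000),
       frac_ge_10kb = mean(len >= 10000))
}
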