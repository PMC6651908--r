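#' Genome model
#'
#' A lightweight container for a reference genome: named nucleotide
#' sequences (upper-case, alphabet A/C/G/T/N) and their lengths.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @return An object of class `GenomeModel` with elements `sequences`
#'   (named character) and `lengths` (named integer).
#' @examples
#' gm <- genome_model(c(chr1 = "ACGTACGT"))
#' gm$lengths
#' @export
genome_model <- function(sequences) {
  if (length(sequences) == 0L) {
    return(structure(list(sequences = character(0),
                          lengths = integer(0)),
                     class = "GenomeModel"))
  }
  nm <- names(sequences)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("all genome sequences must be named")
  if (anyDuplicated(nm))
    stop("duplicate sequence name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("illegal character(s) outside {A,C,G,T,N} in sequence(s): ",
         paste(nm[bad], collapse = ", "))
  structure(list(sequences = sequences,
                 lengths = stats::setNames(nchar(sequences), nm)),
            class = "GenomeModel")
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat("GenomeModel:", length(x$sequences), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read a FASTA file into a GenomeModel
#'
#' Records are upper-cased on load (a message is emitted when lower-case
#' bases are present).  Duplicate record names and characters outside
#' A/C/G/T/N are errors.  An empty file yields an empty model with a
#' warning.
#'
#' @param path path to a FASTA file.
#' @return A [genome_model()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                 error = function(e) stop("FASTA parse error in '", path,
                                          "': ", conditionMessage(e)))
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path)
    return(genome_model(character(0)))
  }
  # FASTA description lines may carry comments after the identifier.
  names(ss) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(ss)))
    stop("duplicate record name(s) in '", path, "': ",
         paste(unique(names(ss)[duplicated(names(ss))]), collapse = ", "))
  seqs <- as.character(ss)
  if (any(grepl("[acgtn]", seqs)))
    message("lower-case bases upper-cased on load: ", path)
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad)) {
    lines <- readLines(path)
    hit <- grep("[^ACGTNacgtn>[:space:]]", lines)[1]
    stop("illegal character in '", path, "' near line ", hit %||% NA)
  }
  genome_model(stats::setNames(seqs, names(ss)))
}

#' Write a GenomeModel (or any named character vector) as FASTA
#'
#' @param x a `GenomeModel` or named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "GenomeModel")) x$sequences else x
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Extract a genomic subsequence (0-based half-open interval)
#'
#' @param genome a `GenomeModel`.
#' @param seqname sequence name.
#' @param start0,end0 0-based half-open interval.
#' @export
genome_subseq <- function(genome, seqname, start0, end0) {
  len <- genome$lengths[[seqname]]
  if (is.null(len)) stop("unknown sequence: ", seqname)
  if (any(start0 < 0L) || any(end0 > len) || any(end0 < start0))
    stop("interval off the end of sequence ", seqname)
  substring(genome$sequences[[seqname]], start0 + 1L, end0)
}
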