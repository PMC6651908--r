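Package: txasmeval
Title: Evaluation Toolkit for De Novo RNA-Seq Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate de novo transcriptome assemblies against a
    reference genome and annotation: read quality-control and deduplication
    rules, depth subsampling, scaffold-to-genome alignment filtering
    (including chimera detection), unique-base genome/exome coverage curves,
    annotated/unannotated scaffold classification with single-exon, intronic
    and open-reading-frame calls, single-scaffold transcript completeness and
    inter-library overlap, and windowed GC-bias diagnostics. Includes a
    synthetic-data generator producing toy genomes, annotations, reads,
    scaffolds and ground truth so every stage can be exercised and validated
    without large sequencing datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
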