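#' Simulation configuration
#'
#' Parameters of the synthetic study system: a toy genome with multi-exon
#' genes, exponentially distributed transcript abundances, optional
#' unannotated (intronic or intergenic, unspliced single-exon) transcript
#' templates, paired error-free reads with configurable fragment-level
#' GC-dependent sampling bias and PCR-duplicate rate, and scaffolds with
#' controlled completeness/fragmentation/chimerism.
#'
#' Length arguments are two-element `c(min, max)` ranges sampled uniformly.
#'
#' @param n_genes number of annotated genes (one transcript per gene).
#' @param n_chromosomes chromosomes to spread genes across.
#' @param exon_count integer range of exons per gene.
#' @param exon_length,intron_length,intergenic_length bp ranges.
#' @param gc_mean range of per-transcript target GC content.
#' @param gc_profile `"constant"` (one GC level per transcript) or
#'   `"segmented"` (GC varies along the transcript in segments, so each
#'   transcript samples a spread of window GC values).
#' @param gc_segment_length segment length (bp) for `"segmented"`.
#' @param background_gc GC of intergenic/intronic background sequence.
#' @param abundance_rate rate of the exponential abundance law
#'   (abundance ~ Exp(rate)).
#' @param n_unannotated number of unannotated transcript templates.
#' @param unannotated_placement `"intronic"` or `"intergenic"`.
#' @param unannotated_length bp range of unannotated templates.
#' @param unannotated_abundance_scale multiplier applied to unannotated
#'   template abundances (these are the low-abundance pool).
#' @param read_length read length (bp).
#' @param fragment_mean,fragment_sd fragment length distribution (bp).
#' @param duplicate_rate probability that an emitted pair is an exact
#'   coordinate copy of an earlier pair (PCR duplicate).
#' @param gc_bias `NULL` for unbiased sampling, or a function `w(gc)`
#'   giving the relative sampling weight of a fragment with GC content
#'   `gc` in `[0,1]`; fragments are accepted with probability proportional
#'   to `w(GC(fragment))`.
#' @param base_quality constant PHRED score assigned to simulated bases.
#' @param n_pairs number of read pairs to simulate.
#' @param spike_in fraction of pairs drawn from a decoy sequence absent
#'   from the genome (unalignable contamination/spike-in reads).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 50L,
                       n_chromosomes = 1L,
                       exon_count = c(2L, 4L),
                       exon_length = c(150L, 350L),
                       intron_length = c(2000L, 5000L),
                       intergenic_length = c(300L, 1500L),
                       gc_mean = c(0.35, 0.65),
                       gc_profile = c("constant", "segmented"),
                       gc_segment_length = 300L,
                       background_gc = 0.42,
                       abundance_rate = 1,
                       n_unannotated = 0L,
                       unannotated_placement = c("intronic", "intergenic"),
                       unannotated_length = c(1000L, 1800L),
                       unannotated_abundance_scale = 0.005,
                       read_length = 100L,
                       fragment_mean = 250,
                       fragment_sd = 30,
                       duplicate_rate = 0,
                       gc_bias = NULL,
                       base_quality = 30L,
                       n_pairs = 10000L,
                       spike_in = 0,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              exon_count = as.integer(exon_count),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              intergenic_length = as.integer(intergenic_length),
              gc_mean = gc_mean,
              gc_profile = match.arg(gc_profile),
              gc_segment_length = as.integer(gc_segment_length),
              background_gc = background_gc,
              abundance_rate = abundance_rate,
              n_unannotated = as.integer(n_unannotated),
              unannotated_placement = match.arg(unannotated_placement),
              unannotated_length = as.integer(unannotated_length),
              unannotated_abundance_scale = unannotated_abundance_scale,
              read_length = as.integer(read_length),
              fragment_mean = fragment_mean,
              fragment_sd = fragment_sd,
              duplicate_rate = duplicate_rate,
              gc_bias = gc_bias,
              base_quality = as.integer(base_quality),
              n_pairs = as.integer(n_pairs),
              spike_in = spike_in,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L,
            all(cfg$exon_count >= 1L),
            all(cfg$exon_length > 0L), all(cfg$intron_length > 0L),
            all(cfg$intergenic_length > 0L),
            all(cfg$gc_mean >= 0, cfg$gc_mean <= 1),
            cfg$abundance_rate > 0,
            cfg$n_unannotated >= 0L,
            cfg$duplicate_rate >= 0, cfg$duplicate_rate <= 1,
            cfg$spike_in >= 0, cfg$spike_in <= 1,
            cfg$read_length > 0L, cfg$fragment_mean >= cfg$read_length,
            is.null(cfg$gc_bias) || is.function(cfg$gc_bias))
  class(cfg) <- "SimConfig"
  cfg
}

#' Preset simulation configurations
#'
#' Named study conditions used throughout the package's validation suite:
#'
#' * `"depth-study"`: a ~2 Mb genome with 200 annotated multi-exon genes
#'   plus 400 low-abundance unannotated intronic single-exon templates and
#'   a 250,000-pair library (50 Mbp).  The annotated (exomic) pool is deep
#'   enough to saturate within the subsample grid while the unannotated
#'   pool stays far from saturation, reproducing the diverging
#'   genome-vs-exome depth-curve phenomenon.  Subsample sizes are carried
#'   in `attr(cfg, "subsample_sizes")` (4 to 40 Mbp, mirroring the shape
#'   of a 1-16 Gbp grid at 1/400 scale).
#' * `"gc-bias"`: 100 single-exon 3 kb transcripts with segmented GC
#'   profiles (windows span GC ~0.35-0.75) and a 300,000-pair library
#'   (~200x mean depth), for windowed depth-ratio bias recovery.
#' * `"gc-bias-constant"`: as `"gc-bias"` but with constant per-transcript
#'   GC, for transcript-level abundance-ratio regression.
#' * `"completeness"`: 60 genes, moderate depth, for completeness and
#'   overlap analyses.
#'
#' @param name preset name.
#' @param seed master seed.
#' @param ... overrides passed to [sim_config()].
#' @return A `SimConfig`.
#' @export
sim_preset <- function(name = c("depth-study", "gc-bias",
                                "gc-bias-constant", "completeness"),
                       seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    "depth-study" = list(
      n_genes = 200L, n_chromosomes = 2L, exon_count = c(3L, 4L),
      exon_length = c(120L, 250L), intron_length = c(2200L, 5000L),
      intergenic_length = c(300L, 1500L),
      n_unannotated = 400L, unannotated_placement = "intronic",
      unannotated_length = c(1500L, 2500L),
      unannotated_abundance_scale = 0.003,
      n_pairs = 250000L),
    "gc-bias" = list(
      n_genes = 60L, exon_count = c(1L, 1L),
      exon_length = c(7000L, 7000L), intergenic_length = c(300L, 800L),
      gc_mean = c(0.35, 0.75), gc_profile = "segmented",
      gc_segment_length = 700L, fragment_mean = 200, fragment_sd = 20,
      n_pairs = 420000L),
    "gc-bias-constant" = list(
      n_genes = 100L, exon_count = c(1L, 1L),
      exon_length = c(3000L, 3000L), intergenic_length = c(300L, 800L),
      gc_mean = c(0.35, 0.75), gc_profile = "constant",
      n_pairs = 300000L),
    "completeness" = list(
      n_genes = 60L, exon_count = c(2L, 4L),
      exon_length = c(200L, 400L), intron_length = c(500L, 1500L),
      n_pairs = 40000L))
  cfg <- do.call(sim_config, utils::modifyList(c(args, seed = seed),
                                               list(...)))
  if (name == "depth-study")
    attr(cfg, "subsample_sizes") <- c(4, 8, 12, 16, 20, 24, 32, 40) * 1e6
  cfg
}
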