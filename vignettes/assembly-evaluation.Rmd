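---
title: "Evaluating de novo RNA-Seq assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating de novo RNA-Seq assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(txasmeval)
```

# The evaluation problem

A de novo transcriptome assembly is a bag of scaffolds with no intrinsic
ground truth. Evaluated against a well-annotated reference genome, three
quantities summarize its scientific value: how much of the *exome* (the
union of annotated exon intervals) the scaffolds recover, how much
*additional* genomic sequence they recover that the annotation does not
explain, and how many reference transcripts are recovered *complete* in a
single scaffold. Layered on top are diagnostics that attribute recovery
failures to sequencing depth (saturation curves) or to library chemistry
(GC-dependent coverage bias). This vignette records the models behind each
stage, the parameters that matter, and the design decisions taken where
more than one reasonable definition exists.

# Coordinate and interval conventions

All internal coordinates are 0-based half-open, everywhere. Conversion
happens only at format boundaries: GFF3 (1-based closed) in
`read_gff3()`/`write_gff3()`, and PSL (0-based half-open, but with
minus-strand query starts stored in reversed-query frame) in
`read_psl()`/`write_psl()`. Minus-strand query coordinates are normalized
to the plus frame on load, so no downstream operation branches on strand
when asking *which query bases are aligned*. Coverage, classification and
completeness are deliberately strand-blind — none of the definitions
involved conditions on strand — while strand is retained for reporting and
for sequence extraction. Interval arithmetic (unions, intersections,
complements) is delegated to IRanges/GenomicRanges; every such operation
is cross-checked in the test suite against brute-force boolean-array
oracles on randomized toy instances.

Sequence-name mismatches between inputs (a PSL target absent from the
genome, a GFF3 feature on an unknown sequence) are hard errors, never
silent drops: the failure modes they indicate (wrong assembly build,
truncated download) corrupt every downstream number.

# Read QC model

A read pair is dropped when **either** mate trips any rule, with the
recorded category being the first tripped rule in the order adapter →
low-quality → ambiguous:

* **low quality**: strictly more than 10% of bases below PHRED 10
  (`phred_cutoff = 10`, `max_low_frac = 0.10`);
* **ambiguous**: strictly more than 1% of bases are N
  (`max_n_frac = 0.01`);
* **adapter**: at least 50% of an adapter matches with at most one
  mismatch (`min_adapter_frac = 0.5`, `max_adapter_mismatch = 1`).

Both "more than" thresholds are strict inequalities, read literally from
the rule set: a 100-base mate with exactly 10 low-quality bases and one N
is kept. Adapter matching is **anchored**: the match must include the
adapter's 5' end and terminate at the read's 3' end. This is the
read-through geometry by which adapter sequence physically enters a read;
an unanchored 6-mer-with-one-mismatch scan would fire on random sequence
at a rate of roughly once per few hundred bases and would make the rule
meaningless. The anchoring choice is recorded in the pipeline run log.

Deduplication collapses pairs sharing (sequence, mate-1 coordinate and
strand, mate-2 coordinate and strand) to the lexicographically smallest
pair identifier — the contract-level semantics of coordinate duplicate
marking, without optical-duplicate distance modelling. The operation is
idempotent. Clean-pair filtering keeps mates on the same sequence, in
convergent orientation, within a configurable span (default 10 kb).

Report tables compute the removal fraction at step *k* as
(count~k−1~ − count~k~)/count~k−1~ — the denominator is the reads
*entering* that step — and aggregate rows sum libraries before dividing.
Counts are in read pairs ("spots"). The shipped UHRR accounting tables are
self-consistent to within 10 ppm per library; one library carries a
570-read discrepancy between its category counts and its filtered total,
which the package surfaces rather than hides (filter categories can
overlap marginally in upstream tools).

# Subsampling and nestedness

`subsample_to_bases()` samples whole pairs uniformly without replacement
until the cumulative base count reaches the target, including the pair
that crosses it. Subsets at increasing targets are prefixes of **one**
seeded permutation, so they are strictly nested. Nestedness is what turns
the coverage and completeness curves into monotone objects: a base covered
at 2 Gbp is covered at 4 Gbp by construction, so curve shape reflects
saturation, not sampling jitter. If a library is smaller than the target,
the whole library is returned with a warning.

# Alignment filtering and the chimera rule

A scaffold is *retained* when its single best alignment — most matched
bases, ties broken by fewest blocks, then lexicographic target name —
covers at least 98% of the scaffold length, counting summed block lengths
of that one alignment (`min_fraction = 0.98`, a `>=` threshold, so
exactly 98% passes and 97.9% fails). Computing the fraction from one
alignment rather than the union of all alignments is what gives the
chimera filter meaning: a scaffold whose alignment *union* reaches 98%
while no single alignment does is labelled *chimeric* (its halves align
to different loci); everything else is *low quality*. Every scaffold
receives exactly one verdict. Downstream stages use only retained
scaffolds' best alignments (`best_hit_only = TRUE`), so multi-mapping
scaffolds never double-count genome bases.

# Coverage curves

`unique_base_coverage()` counts each genome position covered by at least
one retained alignment block exactly once; the exome count intersects
that union with the **global** exon union. (An alternative would restrict
exome counting to exons of the best-matching transcript; the global union
is used because the quantity of interest is "annotated sequence
recovered", irrespective of which transcript explains it.) Curves are
normalized by the exome coverage of the largest subsample, so the exome
track ends at exactly 1 and the genome track's endpoint reads directly as
"genomic sequence recovered per unit of annotated sequence".

`coverage_curve()` needs per-subsample scaffold coverage without running
an assembler. The stand-in is read-placement coverage: the genome
positions covered by at least `min_depth` reads of the subsample
(default 1). This preserves exactly the property the curve measures —
which positions have been sampled at a given depth — while sidestepping
assembler behaviour, which is out of scope.

# Scaffold classification

The annotation fraction of a scaffold against a transcript is
`max(overlap/scaffold_length, overlap/transcript_length)` with overlap
counted in aligned bases falling in that transcript's exon set — the
denominator is whichever is more favorable, so a fragment fully inside a
long transcript and a complete scaffold with UTR overhang both score
high. A scaffold is *annotated* at threshold *t* iff its best fraction is
**strictly** greater than *t*/100; the annotated count is therefore
monotone non-increasing along the 0–100% grid, which the suite asserts.
Headline SE/SEI/ORF proportions are reported at a designated threshold
(default 80%) alongside the full sweep.

Exon structure: adjacent target blocks separated by a target gap of at
least `min_intron_gap = 30` bases, with essentially no query-side gap
(`max_query_gap = 10`), are exon boundaries. The 30 b floor sits below
essentially all real introns and above typical assembly indels; both
knobs are configurable because no universal constant exists. An
unannotated single-exon scaffold is *intronic* when strictly more than
half of its aligned bases fall in the global intron union; exact ties are
non-intronic. The global union is used (rather than introns of a
particular gene) because the question is "does this material look like
unprocessed intronic RNA", not "which gene does it belong to".

ORFs require an ATG start and an in-frame stop, counted in amino acids
including the initial methionine and excluding the stop, across all six
frames; the flag is ≥100 aa, and scaffolds shorter than 300 b are excluded
from ORF denominators. A stop-to-stop mode is available behind a flag for
analyses that do not want to require an annotated start. The scanner is
validated against an exhaustive codon-walking oracle on random sequences.

# Completeness and overlap

A reference transcript is *complete* when some scaffold, whose top
alignment score is **strictly** greater than its second best (ties
disqualify the scaffold — the literal reading of "unambiguous top-scoring
alignment"), covers at least 95% of the transcript length with the union
of aligned positions of that single alignment. Internal gaps do not
count; alignment intervals extending past the transcript end (UTR-bearing
scaffolds) are clamped with a warning rather than rejected, since a
complete assembly is legitimately longer than its annotation.
Transcript-space alignments may be supplied directly or derived from
genome-space PSL by projection through the exon structure
(`project_to_transcripts()`); scores are block-length totals.

The overlap matrix is row-normalized: entry (r, c) is
|complete(r) ∩ complete(c)| / |complete(r)|, generally asymmetric, with
empty-row entries reported as missing rather than 0.

`completeness_by_size()` again needs an assembler stand-in: a
transcript's scaffold is its **longest contiguous read-covered run** in
transcript space, because no overlap-based assembler can join across a
zero-coverage gap. Complete-transcript counts are then monotone
non-decreasing under nested subsets.

# GC-bias diagnostics

Gap regions are transcript positions covered by neither scaffold
alignments nor any reads; transcripts enter the comparison only with at
least 10 gap bases. GC cumulative distributions of assembled vs. gap
regions are **length-weighted** empirical CDFs of per-region GC computed
on the reference transcript sequence (the scaffold sequence does not
exist for gaps, so the reference is the only symmetric choice); a
windowed-GC alternative sits behind a flag-free helper the user can call
directly.

The bias-transcript set keeps transcripts with zero genomic overlap with
any other transcript and mean raw-position depth ≥10 in every compared
dataset; a Spearman correlation between 1%-segment GC histograms of the
selected vs. all transcripts quantifies representativeness. The bias
curve tiles each transcript with non-overlapping 100 b windows from the
5' end (a trailing partial window is discarded), bins windows by integer
GC percent, and averages window-depth/transcript-mean-depth ratios per
bin; transcript mean depth is over raw positions, not windows. The
window-count-weighted mean of bin means equals the global mean ratio,
which is 1 exactly under uniform depth.

TPM estimation is direct counting: rate = count/length, TPM = 10^6 ·
rate/Σrate. No expectation-maximization quantifier is reimplemented:
synthetic reads are unambiguously assignable by construction, making
direct counting exact, and externally quantified abundance tables can be
supplied as named vectors. The abundance-ratio regression includes
transcripts with TPM ≥ 10 in **both** libraries and fits ordinary least
squares of log10(TPM₁/TPM₂) on GC fraction; OLS is the estimator because
the relationship being probed is a log-linear trend, and the slope's
standard error is reported for calibrated comparison against an injected
bias.

# What the synthetic generator emulates

`sim_config()`/`sim_preset()` define the study conditions:

* **Gene models**: multi-exon genes with uniform exon/intron/intergenic
  length ranges; one transcript per gene (no isoform families).
* **Abundances**: exponential with rate λ (default 1) — the canonical
  skewed-expression model; true TPM is the molecule-space normalization.
* **Unannotated transcription**: single-exon unspliced templates placed
  inside introns (the "unprocessed pre-mRNA" default) or intergenically,
  at a configurable abundance scale — the low-abundance reservoir that
  keeps genome coverage climbing after the exome saturates.
* **Reads**: error-free pairs in FR orientation; fragments drawn with
  probability ∝ abundance × w(GC(fragment)) by rejection sampling, where
  w is any user bias function (fragment-level, because that is where
  library-prep bias physically acts); duplicates injected as exact
  coordinate copies; optional spike-in pairs from a decoy sequence absent
  from the genome.
* **Scaffolds**: per transcript, a configurable covered fraction with
  optional genomic UTR-like flanks; chimeras concatenate two transcripts
  in a 60/40 split so that no single alignment can reach the 98% filter
  while the union always does.

Reads are error-free by default; QC filters are exercised on separately
constructed corrupted reads, keeping bias analyses clean.

Two generator details exist purely to make fragment-level bias
*identifiable* at window scale, and are worth understanding before using
`gc_profile = "segmented"`. First, segmented profiles are built from
100 b units with exact GC composition, so a window's measured GC equals
its segment's target exactly — with fully random sequence, the ±5% noise
of 100 b windows regresses extreme bins toward the mean and attenuates
any recovered curve. Second, every transcript carries the same evenly
spaced GC levels in shuffled order (a stratified design), so the
per-transcript mean sampling weight — the denominator of every depth
ratio — is constant across transcripts; without this, transcripts
carrying a high-GC segment systematically have lower mean weight, which
inflates high-GC bins. Neither trick changes what the *measurement* does
on real data; they remove confounds from the *calibration* data. Real
libraries, of course, offer no such guarantees — sequencing errors,
isoforms, overlapping genes, mappability and fragment-length biases are
all absent here, so passing recovery tests demonstrates correctness of
the measurement chain, not robustness to every artefact of real data.

## Study problem sizes

The validation suite runs at deliberately modest scale, chosen so that
each phenomenon is statistically unambiguous: the depth study uses a
~2 Mb genome (200 genes of 3–4 exons at 120–250 b, introns 2.2–5 kb, 400
intronic templates of 1.5–2.5 kb at abundance scale 0.003) with a
250,000-pair library subsampled at 4–40 Mbp — the annotated pool
saturates inside the grid while the unannotated pool stays in its
near-linear sampling regime, reproducing the diverging genome/exome
curves. GC-bias runs use 60 single-exon 7 kb transcripts at ~200× mean
depth (420,000 pairs), giving ≥50 windows in every populated GC bin.
Classification truth recovery uses 40 genes, 25 intronic templates and 8
chimeras.

# Numerical and degenerate-input choices

* Thresholds: alignment retention and completeness are `>=` on stated
  fractions; annotation ("greater than that percentage") and the intronic
  majority are strict `>`.
* Tie-breaks: best alignment by matches, then fewest blocks, then target
  name; completeness disqualifies tied top scores when ambiguity checking
  is on, includes all tied candidates when off; duplicate representatives
  are the smallest pair identifier.
* Degenerate inputs: empty FASTA warns and yields an empty model; empty
  alignment sets yield zero coverage; empty complete sets yield NA
  overlap rows; transcripts shorter than one window, or with zero depth,
  are skipped with a message; all-N regions are skipped in GC CDFs;
  libraries smaller than a subsample target return whole with a warning.
* Seeding: every randomized stage takes one seed; per-stage seeds are
  derived deterministically from it, so a pipeline run is reproducible
  end to end and subsample nestedness survives re-execution.

# Known limitations

* The assembler stand-ins (coverage union; longest covered run) bound
  what a real assembler could do from the sampled reads; they do not
  model mis-assembly, fragmentation heuristics or gap filling.
* Kallisto-style probabilistic quantification, BAM output, plateau-point
  estimation, coding-potential scoring and homology search are out of
  scope; external tools' outputs can be imported where relevant.
* The completeness "pooled beats singles" behaviour requires genuinely
  complementary libraries; the suite emulates complementarity with
  per-library transcript dropout, since statistically identical libraries
  pooled and resampled are indistinguishable from any single library.
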