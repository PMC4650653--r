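---
title: "Auditing synthetic long reads against a finished genome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing synthetic long reads against a finished genome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longreadaudit)
```

## What the package measures

Synthetic long reads (1.5–23 kb sequences preassembled from barcoded short
reads of single long DNA molecules) promise to close gaps and recover
repeats that defeat short-read sequencing. `longreadaudit` evaluates such
reads against a finished reference genome along five axes:

1. **Per-read accuracy.** Every alignment's CIGAR string and MD tag are
   decomposed into SNVs, insertions and deletions relative to the
   reference; rates are expressed per aligned base and profiled along 100
   windows of normalized read length, with indels split at the 9 bp
   long-indel cutoff.
2. **Missing-sequence recovery.** Insertions in reads relative to the
   reference indicate sequence absent from the assembly. Four detection
   modes are implemented: *within-read* (a CIGAR I op inside one
   alignment), *self-mapped* (a soft-clipped "unaligned end" re-anchored
   locally at relaxed stringency; the un-anchored middle is the
   insertion), *cross-mapped* (the overlapping unaligned ends of two
   adjacent reads merged into one sequence), and *close-breakpoint* (two
   non-overlapping ends joined across an unknown-length gap). Calls are
   merged across modes and annotated as coding-exon, intronic or
   intergenic.
3. **Length-stratified coverage.** Median and N50 read lengths, 100 bp
   length strata (139 closed bins plus an open bin above 15.4 kb), and
   accumulative coverage curves using only the reads shorter than, or at
   least as long as, each candidate split length, with the intersection
   point of the two curves.
4. **Repeat behaviour.** Full-length recovery rates per repeat class under
   nested coverage subsampling; enrichment and composition of repeat
   classes inside zero-coverage gaps; detection of tandem clusters of a
   short unit, flagged as preassembly blockers above 500 bp; and
   copy-number estimation for collapsed repeats from relative read depth.
5. **Assembly assessment.** Contig N50/L50, misassembly classification
   (relocation, translocation, inversion), NA50/LA50 after breaking
   contigs at misassembly junctions, duplication ratio, genome/gene/repeat
   coverage and per-100 kb variant rates, computed from a block-level
   contig-to-reference alignment table.

## The synthetic data generator

Real synthetic-long-read datasets are large and external; the package
instead ships a seeded generator whose outputs exercise every stage with
known truth. It is first-class, tested code, not a fixture.

**Reference.** Each chromosome is unique random sequence interleaved with
interspersed repeat copies (DNA, LINE, SINE, LTR, RC/Helitron classes),
tandem clusters of a single short unit (e.g. a `TGATA` simple repeat) with
cluster lengths placed on both sides of the 500 bp blocker threshold,
exactly one copy of a collapsed-repeat unit (7.2 kb by default, the scale
of an rDNA unit), and protein-coding gene models with exons and introns in
unique sequence.

**Donor.** The sequenced genome differs from the reference by injected
SNVs, insertions of 9–2000 bp (drawn log-uniformly; these model sequence
*missing* from the reference) and deletions, all placed in unique or genic
sequence at least 3 kb apart, plus an expansion of the collapsed unit to
*k* tandem copies (default 20). Every event is recorded with a canonical
left-aligned breakpoint, its genomic context, and its expected detection
regime: `cigar` for insertions at most 100 bp, `clip` otherwise.

**Reads.** Lengths follow a two-component truncated-normal mixture (means
1.8 and 9.8 kb, weights 0.35/0.65, truncated at 1.5 kb) reproducing the
bimodal length distribution of preassembled long reads; the peaks near
1.5 and 10 kb are the anchors, the spreads are our choice.
The read count is the target yield divided by the closed-form mixture
mean. Fragment starts are uniform along the donor with overhang at
chromosome ends truncated (never below 1.5 kb), so expected depth is
uniform out to the ends — a random shearing of a linear chromosome does
produce terminal fragments. Sequencing errors are applied per base at
configurable event rates (defaults 0.01% SNV, 0.02% insertion, 0.10%
deletion — the deletion excess mirrors what is observed in real
preassembled reads), multiplied 5× inside the outer 5% of each read to
model end-elevated error, with error indel sizes of 1–8 bp. A configurable
fraction of deletion errors is targeted into annotated repeats, modelling
the observation that read deletions concentrate in repetitive sequence.
Quality strings encode the two-zone error model.

**Aligner emulator.** Instead of bundling an aligner, alignments are
*projected*: each read's known donor interval is mapped through the
donor–reference block table. A donor insertion of size *s* spanned with
both read flanks ≥ 1 kb (the minimum-seed analogue) becomes a CIGAR I op
when *s* ≤ 100 bp; otherwise the longer flank anchors the primary
alignment and the remainder of the read becomes a soft clip — exactly the
"unaligned end" substrate of the recovery modes. Primary matches are
extended maximally into the clip while bases agree, as a real aligner
would, so recovered breakpoints stay canonical. Reads carrying more than
500 bp of a blocked tandem cluster are withheld entirely, emulating
preassembly failure over low-complexity tandem arrays (a read fully inside
such a cluster is the limiting case); this produces the zero-coverage gap
in the cluster interior. Reads over the expanded collapsed repeat are
wrapped onto the single reference copy as split (primary + supplementary)
records, producing the depth spike used for copy-number estimation. MD
tags are computed by sequence comparison, so SNVs and read errors surface
exactly as they would from a real aligner.

With a fixed seed every artifact (FASTA, FASTQ, SAM, truth tables) is
byte-identical across runs.

### What the generator does not model

Barcoding wells and the string-graph preassembly itself, PCR chimeras,
GC-coverage bias, heterozygosity, and alignment mapping ambiguity in
repeats (the emulator knows the true origin of each read). Passing tests
therefore demonstrate that the *analysis* stages are correct given
well-formed alignments, not that any particular aligner's quirks are
handled; real SAM from any aligner remains valid input.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_len` | 1500 | bp | reads shorter than this are not produced/retained |
| `long_cutoff` | 9 | bp | long-indel boundary used for size classes and insertion promotion |
| `max_cigar_insertion` | 100 | bp | emulator regime boundary between I-op and soft-clip representation |
| `min_anchor` | 1000 | bp | flank needed for an I-op representation (minimum-seed analogue) |
| `blocker_threshold` | 500 | bp | tandem-cluster length above which preassembly fails |
| `relax_min_anchor`, `relax_min_identity` | 200 bp, 0.90 | | relaxed re-anchoring of unaligned ends |
| `min_overlap`, `min_overlap_identity` | 30 bp, 0.95 | | clip-overlap acceptance for cross-mapped merging |
| `pair_max_distance` | 50 | bp | maximum breakpoint distance between paired ends |
| `merge_tolerance` | 10 | bp | breakpoint clustering distance for call merging |
| `flank` | 2500 | bp | validation-contig flank on each side |
| `confirm_depth` | 10 | × | per-base junction depth for a confirmed insertion |
| `exon_depth` | 2 | × | RNA-seq depth defining an exonic run |
| `relocation min_gap` | 1000 | bp | reference discontinuity defining a relocation |
| `coverage_levels` | 3, 6, 12, 24 | × | nested subsampling depths |

## Statistical and numerical choices

**Variant calling rule.** A site is called when depth ≥ 1, support ≥ 1 and
support/depth > 0.5. This renders a probabilistic caller's "minimum
coverage 1, minimum count 1, probability > 0.5, ploidy 2" configuration as
a transparent support-fraction rule; it is an emulation of that behaviour,
not a likelihood model.

**Left alignment.** All indels — injected truth, per-read events and
recovered insertions — are shifted to their leftmost equivalent placement
against the reference before comparison or merging. Without this,
homopolymer and tandem contexts fragment support across equivalent
placements.

**Error ratios.** Both event-count and event-base ratios per aligned read
base (M/=/X) are computed: an 8 bp deletion counts once in the former and
eight times in the latter. The simulator's configured rates are event
rates, so parameter-recovery checks use the count ratio; the base ratio
reproduces the deletion ≫ SNV asymmetry seen in real data.

**Merging recovered insertions.** Calls whose breakpoints fall within
10 bp of each other describe the same missing-sequence event (injected and
real insertions are far sparser than this); the call of highest precedence
(within-read > self-mapped > cross-mapped > close-breakpoint) represents
the cluster and read support is unioned. Sequence comparison decides only
whether equal-precedence gap-free calls genuinely conflict, and uses a
local alignment so that a few indel-walk artifacts at the clip boundary do
not split one event in two. Merging is idempotent.

**Anchoring unaligned ends.** The self-mapped detector re-anchors a clip
with 48-mer seeds every 200 bp (each seed matched independently against
the reference window, tolerating 2 mismatches), refines to the deepest
anchored seed, and walks base-by-base toward the split, stopping at an
error cluster (3 mismatches within 8 bases). Independent seeds make the
anchor robust to indel errors in the flank; on error-free data the
recovered sequence and breakpoint are exact. The coarse/fine seed scan
costs O(clip/200) pattern matches instead of O(n·m) dynamic programming.

**Ties and degenerate inputs.** The shorter/longer split is `length < L`
vs `length ≥ L`; curve-intersection ties resolve to the smaller L (with a
1e-12 tolerance against floating-point noise); empty read sets, empty
contig sets, zero aligned bases and coverage requests beyond the available
depth are errors; an empty gap set yields an empty enrichment report, not
an error; a copy-number region spanning the whole genome falls back to the
naive mean so the identity answer of 1 is still produced.

**Copy number.** Mean depth over the region divided by mean depth outside
it, excluding the queried region and zero-depth bases from the genome mean
to avoid self-dilution; the naive genome-wide mean is reported alongside.
The region's depth track includes supplementary records because reads from
the expanded copies align to the single reference copy as split records.

**Subsampling.** Reads are permuted once per seed and nested prefixes are
taken to reach each target depth, so the 3× set is contained in the 6× set
and recovery is monotone in coverage by construction.

## Problem sizes used in tests

The shipped tests run the generator at 120–400 kb genomes for module
checks, and at the study-like conditions for the acceptance properties:
a 2 Mb genome at 24× for error-rate recovery (≈48 Mb of aligned bases,
giving 3-SE bands of ±4% relative for the SNV rate and ±1.3% for the
deletion rate), 1.2 Mb at 12× with 50 injected insertions of 9–2000 bp
for recovery checks, and 300–500 kb genomes for the positional, tandem-gap,
subsampling and copy-number properties. These sizes were chosen so the
binomial error bands are tight enough to be discriminating while the whole
suite stays comfortably interactive.

## Known limitations

* The aligner emulator never misplaces a read; mapping ambiguity in
  near-identical repeat copies — a real failure mode — is out of scope.
* Close-breakpoint calls carry a lower-bound size only; their gap is
  rendered as 100 N's in VCF output with a `GAPPED` flag.
* "Complex variation" (mixed adjacent events) is not emitted as a
  category; such events are reported as their primitive parts.
* The validation stage emulates short-read mapping by projecting reads
  onto validation contigs whose junction sequence occurs in the donor;
  it does not model mapping errors or library-fragment-size effects.
* Multi-mapping reads are resolved primary-only before variant calling;
  supplementary records can be included in depth tracks by flag.
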