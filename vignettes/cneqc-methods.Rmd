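---
title: "Methods: conserved-element assembly QC and CNE classification"
author: "cneqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved-element assembly QC and CNE classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cneqc)
```

# Scope and data model

`cneqc` assesses genome assemblies through the lens of conserved sequence:
how many deeply conserved elements an assembly contains, whether
evolutionarily linked neighbors stay linked on its scaffolds, and how a
reference-anchored multiple alignment partitions conserved non-exonic
elements (CNEs) into lineage-specific and shared classes.

Sequences are held in `Biostrings::BStringSet` rather than `DNAStringSet`
because soft-masking case must survive I/O: lowercase marks
repeat-annotated bases, which are ordinary nucleotides everywhere except
`maskedFraction()`. Intervals are `GenomicRanges::GRanges` (1-based
closed, the Bioconductor convention); the 0-based half-open conventions of
BED and PAF, and MAF's strand-relative starts, are converted exactly once,
inside the format readers and writers. All interval arithmetic is
strand-agnostic — strand is carried as annotation but never used in
`mergeIntervals()`, `subtractIntervals()` or overlap queries.

# Assembly statistics

An assembly gap is a maximal run of at least `minRun` ambiguous bases
(default 25; other projects use other conventions, hence the parameter).
Contigs are the gap-free pieces, so contig bases + gap bases = scaffold
bases by construction, a conservation law the tests assert on random
input.

N(x) is the largest length L such that sequences of length ≥ L jointly
cover at least x% of the total. It is computed by descending sort and
cumulative sum, with the threshold compared as
`100 * cumsum >= x * total` so that boundary ties are decided in exact
integer arithmetic rather than floating-point percentages (integer-valued
doubles are exact far beyond genome scale). The N(x) curve is evaluated
at every x in 1..99 and is non-increasing by construction. Whether contig
statistics should split scaffolds at every N or only at gap-length runs
is genuinely convention-dependent; the default follows the ≥ 25 rule and
`minRun` overrides it.

`maskedFraction()` divides lowercase bases by *all* bases (N included in
the denominator only), matching the usual "fraction of the genome
annotated as repeat" phrasing.

# Element completeness

A reference element set is prepared with `prepareCneReference()`: only
elements strictly longer than 300 bp are retained and 30 bp are trimmed
from each end, because the element *core* is what stays alignable across
large distances; survivors are therefore ≥ 241 bp. Both thresholds are
parameters.

Elements are located either by an external aligner (PAF input with a
`cg` cigar) or by the built-in `mapElements()`: exact `seedLen`-mer
anchors (default 12, both strands) followed by ungapped full-length
scoring clipped at scaffold ends. The mapper is deliberately ungapped —
the divergence regimes it serves are substitution-dominated, and a
planted element is guaranteed a perfect hit. It is not a general-purpose
aligner and makes no attempt at gapped or split alignment.

Hits are filtered at identity ≥ 0.60 and coverage ≥ 0.80, both inclusive.
"Alignment identity" has no single community definition when gaps are
involved; the default counts gap columns in the denominator
(`matches / (matches + mismatches + gaps)`), the stricter choice, with
`identityMode = "gap-exclusive"` available. Coverage is query-side only
(aligned fraction of the element), since the element is the unit being
"found". The best hit per element is chosen by identity × coverage, ties
by match count, remaining ties by lexicographically smallest target
coordinate — a total order, so the result is independent of hit input
order.

# The conserved-pair contiguity statistic

`buildReferencePairs()` defines pairs from per-outgroup element
locations: within each outgroup, elements are sorted by coordinate and a
candidate pair is two *consecutive* elements on the same chromosome at
inner (end-to-start) distance ≤ 1 Mb. A pair is emitted only if it is a
candidate in every provided outgroup — that conjunction is what makes the
neighborhood evolutionarily conserved. Consecutiveness (rather than
all-vs-all within the window) is the natural reading of "neighboring",
and it lets one element participate in two pairs (A–B and B–C), which we
judge harmless for a recovery statistic; a matching-based disjoint
pairing would only shrink the denominator.

`evaluatePairs()` then scores each pair in the assembly under test:
`recovered` if both elements' best hits share a scaffold at inner
distance ≤ 1 Mb, `unmapped` if either element has no retained hit,
`split` otherwise. Inner distance between hit spans (not midpoints) is
used because it is stable under element-length changes; overlapping hits
count as distance 0. On a single-scaffold assembly containing all
elements the statistic is exactly 100%, and fragmentation can only
remove pairs — the property suite verifies the mean recovery is
non-increasing over 0, 5 and 20 random breaks across 20 simulation
seeds.

# CNE derivation and lineage classification

The pipeline composes five steps, each independently testable:

1. **Merge** (`mergeConservedSets()`): union of two conserved-region call
   sets (standing for two independent constraint callers), joining
   regions separated by ≤ 10 bp and dropping merged regions < 30 bp. The
   gap between intervals is the count of bases strictly between them, so
   abutting intervals join at any setting.
2. **Support windows** (`computeSupportWindows()`): per species and MAF
   block, every run of 30 consecutive reference-base columns with
   pairwise identity ≥ 60% marks its reference positions; marked
   positions merge into maximal intervals and only intervals ≥ 30 bp are
   reported. Columns where the reference is gapped are skipped entirely;
   a species gap column counts as a non-match over the full 30-column
   denominator (gap-inclusive; the exclusive variant drops gap columns
   from the denominator). Negative-strand reference rows are rejected
   rather than silently mis-projected; non-reference rows may be either
   strand since only their column characters matter.
3. **Species support** (`speciesSupportFilter()`): a region is kept if it
   overlaps windows of at least 4 distinct species. Overlap is ≥ 1 bp by
   default (`minWindowOverlap`); the explicit 30 bp minimum elsewhere in
   the pipeline applies to transposon overlap, not here, and any stricter
   choice is a parameter away.
4. **Exon subtraction** (`deriveCnes()`): exonic bases are subtracted and
   fragments ≥ 30 bp become CNEs, each recording its parent region. A CNE
   base is therefore always a conserved, non-exonic base (bitmap-checked
   in the tests).
5. **Classification** (`classifyLineage()`): ingroup-specific requires
   window overlap in ≥ 6 of the ingroup species and in *zero* outgroup
   species; shared requires ≥ 6 ingroup and ≥ 1 outgroup; everything else
   is unclassified. The three classes partition every input, which the
   tests assert on random window sets.

Transposon accounting restricts the repeat annotation to SINE, LINE, LTR
and DNA classes (RepeatMasker class strings are normalized by stripping
`?` qualifiers and truncating at `/`; anything else becomes `other`). A
CNE counts as transposon-overlapping when a *single* feature overlap
reaches 30 bp — "overlaps a transposon by ≥ 30 bp" reads per-feature —
with `sumOverlaps = TRUE` switching to the per-CNE total. The report
gives the qualifying count, transposon-covered CNE bases overall and per
class, and the fraction of all CNE bases explained.

# The clade simulator

`simulateClade()` exists so that every stage above can be exercised
against a planted truth with no external data. Its default configuration
is the package's standing study condition: a 200 kb uniform-composition
reference carrying 50 elements of 150–350 bp (one per 4 kb slot, keeping
placement trivially collision-free), 9 ingroup species at per-branch
substitution probability 0.05 and 3 outgroups at 0.15 — divergences
chosen so conserved loci sit comfortably above the 60% window threshold
while remaining clearly non-identical. Elements are 40%
ingroup-specific (outgroup loci overwritten with unrelated random
sequence), 40% shared, 20% decoys (overwritten in all but 2 ingroup
species, below the 4-species support threshold). Conserved-region calls
are emitted as two sets that overlap or abut with ≤ 10 bp gaps so the
merge step is actually exercised, plus sub-30 bp noise calls that the
length filter must drop. Twenty exons (60–200 bp) sit in element-free
zones, three of them deliberately clipping an element's leading 40 bp to
exercise exon subtraction; four transposons are planted to overlap a
non-decoy element by 61 bp, the rest are background.

Evolution is substitution-only (Jukes–Cantor-style uniform replacement).
This is the simulator's central simplification: with no indels, the true
alignment is positional and MAF blocks can be emitted without running an
aligner, and the built-in ungapped mapper is exact. Consequently, passing
tests demonstrate correctness of the *accounting* — filters, thresholds,
classifications, statistics — not robustness to indel-rich alignment,
rearrangement, duplicated elements or realistic repeat landscapes, none
of which the generator produces.

Determinism: every output draws from its own RNG stream derived from
(seed, stream name) through a small string hash, so adding an output
never perturbs existing ones; identical seeds yield byte-identical files,
asserted by checksum in the tests.

With an expected ~0.25 identity, an unrelated 30-column window passes the
60% threshold with probability ~1e-5, so a replaced locus very
occasionally acquires a spurious support window; this is why label
recovery is asserted at ≥ 95% rather than 100% over the 20-seed sweep
(observed ~98%), while the zero-tolerance assertion — no planted shared
element ever called ingroup-specific — holds exactly, because shared loci
always retain genuine outgroup support.

# Numerical and degenerate-input choices

- Percentages are rounded half away from zero to one decimal
  (`roundHalfUp()`, `percentOf()`); raw counts always accompany rounded
  figures in reports.
- `nxValue()` errors on empty input; `findGaps()` of a gap-free assembly
  is an empty `GRanges`, and a scaffold consisting entirely of Ns
  contributes zero contigs.
- Zero-length queries and hits with no aligned bases are errors, not
  NaNs, in `hitIdentity()`/`hitCoverage()`.
- A pairwise alignment column gapped on both rows is malformed and
  rejected (`summarizeDifferences()`), and difference percentages are
  reported over reference bases — including the insertion percentage,
  whose inserted bases are by definition not reference bases; this keeps
  a single denominator across all three difference classes.
- BED, PAF, MAF and RepeatMasker readers fail fast with the offending
  line or block number; coordinates are validated before conversion.
- Entropy in `passesEntropyQuality()` is Shannon entropy in bits of the
  query-base composition (gaps excluded) over the window; identity and
  entropy must hold over one common run of ≥ 30 columns, checked by
  exhaustive window enumeration.

# Problem sizes in the test suite

The suite runs the oracle-equivalence sweeps at 1,000 random instances
per operation (≤ 10 kb interval bitmaps, ≤ 500-column alignments), the
label-recovery and contiguity sweeps at 20 seeds of the default 200 kb /
50-element / 12-species configuration, and determinism checks on full
fixture directories. These sizes keep the complete suite in the
single-digit-minute range on one CPU while leaving every statistic far
from small-sample degeneracy.

# Known limitations

- The built-in mapper is exact-seed and ungapped; diverged elements whose
  every seed is disrupted are invisible to it, and gapped homology is out
  of scope (use an external aligner and PAF input instead).
- MAF handling requires the reference row on the forward strand; the
  general reverse-strand reference projection is intentionally not
  implemented.
- `buildReferencePairs()` treats element locations as unique per
  outgroup; paralogous multi-placement must be resolved upstream.
- The simulator does not model indels, rearrangements, GC heterogeneity
  or realistic repeat families; conclusions about real-data robustness
  should not be drawn from its recovery rates.
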