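---
title: "Haploblock detection and companion analyses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haploblock detection and companion analyses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploblocks)
```

# The problem

Wheat and its wild relatives (the *Aegilops*/*Triticum* group) carry
genomes of several gigabases whose chromosomes exchange and retain long
stretches of near-identical sequence across species boundaries. Locating
those stretches — *haploblocks* — between a pair of chromosome-scale
assemblies tells a breeder which regions of a wild relative are already
represented in wheat and which harbour untapped variation. The same
genome-panel studies routinely need three companion computations:
labelling predicted genes by annotation confidence, reconciling two
independent routes to NLR disease-resistance loci, and summarizing
orthogroup sharing across the panel. This package implements the four
analyses with explicit, tested semantics, plus simulators that replace
the multi-gigabase inputs with seeded fixtures of known truth.

# The haploblock model

The input is a set of local alignments between one reference and one
query genome, each with a percent identity
$p = 100 \cdot \mathrm{matches} / \mathrm{aligned\ bases}$. The caller:

1. **filters** alignments with reference span below `minAlnLen`
   (default 20 kb — short alignments are dominated by repeats and
   spurious seeding);
2. **bins** each surviving alignment into the fixed 5-Mb bin (grid
   anchored at position 0) containing its reference midpoint
   $\lfloor (s+e)/2 \rfloor$, so every alignment is a single
   observation of local identity;
3. computes each bin's **unweighted median** identity, rounded half-up
   to `medianRounding` (default 2) decimals;
4. **merges** adjacent non-empty bins into blocks; and
5. **drops** blocks whose median does not exceed `identityCutoff`
   (strict by default) or with fewer than `minBins` bins.

Two merge rules are shipped because the two natural readings of
"adjacent bins that agree" are not equivalent, and both are useful:

* `identical_median` (default): maximal runs of bins whose *rounded
  medians are equal*; the block median is that shared value. This is the
  conservative rule — with noisy identities it fragments into shorter
  blocks, because two bins agree only to the rounding quantum.
* `threshold`: maximal runs of bins *each exceeding the cutoff*; the
  block median is the median of the constituent bin medians. This is the
  rule that matches "a median identity of > 95 % along the region" and
  is robust to sub-quantum noise.

Median equality is evaluated **after** rounding because floating-point
medians are almost never bitwise equal; the quantum (default 0.01
percentage points) is the resolution at which two bins can be called
"the same ancestry". Empty bins (no alignment surviving the filter)
terminate every run: absence of alignment is absence of evidence, and a
haploblock is by definition contiguous.

Per-pair cutoffs follow practice for this genome group: 99 % for very
close pairs (e.g. *Ae. longissima* vs *Ae. sharonensis*) and 95 %
otherwise. The cutoff comparison is strict (`>`), matching the usual
"> 95 %" phrasing, with `cutoffStrict = FALSE` available. The length
filter default is 20 kb; 10 kb is in circulation for the same analysis
and is one parameter away (`minAlnLen = 10000`).

Coordinates are 0-based half-open at every file boundary (BED, the
show-coords conversion `start-1/end`, PAF pass-through) and 1-based
closed inside GRanges containers, as is standard for Bioconductor;
accessors and writers do the conversion so users never handle it.

## Downstream interval operations

`genomeCoverage()` is covered bases over total genome length (blocks are
disjoint by construction). `intersectHaploblockSets()` reduces each
pairwise block set and intersects across sets, yielding the maximal
regions shared by *every* query against a common reference — the
multi-genome panels of a cross-species comparison.
`associateIntervals()` assigns a feature to the block with the largest
overlap (ties to the leftmost), with ≥ 1 bp overlap required; this is
how single-copy NLRs are tied to specific haploblocks.

# Gene-confidence rules

Predicted proteins are classified from best hits against three
databases: UniMag (curated Magnoliophyta proteins), UniPoa (Poaceae
proteins) and PTREP (transposon proteins). A hit qualifies when its
E-value is strictly below `evalueMax` (default 1e-10) and the
db-appropriate coverage strictly exceeds `covMin` (default 95 %):
subject coverage for the protein databases, query coverage for the
transposon database. With C = complete protein (start and stop codon),
M/P/T = qualified hit per database, in precedence order:

| C | M | P | T | label |
|---|---|---|---|-------|
| 1 | 1 | · | · | HC |
| 1 | 0 | 1 | 0 | HC |
| 1 | 0 | · | 1 | REP |
| 1 | 0 | 0 | 0 | LC |
| 0 | · | M∨P | 0 | LC |
| — | — | — | otherwise | UNCLASSIFIED |

Two readings of the prose rules are genuinely ambiguous and are exposed
as parameters rather than silently chosen. First, the UniMag HC clause
demands both subject *and* query coverage (the strict qualifier), while
the generic rule uses subject coverage only; a UniMag hit qualifying on
subject but not query coverage therefore blocks every other label and
yields UNCLASSIFIED — the conservative outcome. Second, whether the
UniPoa HC clause requires completeness is controlled by
`hc2RequiresComplete` (default TRUE, the conservative reading). The
E-value threshold is likewise configurable because "below 10e-10" is
ambiguous between 1e-9 and 1e-10; the default is 1e-10, consistent with
the 1e-X convention used elsewhere in such pipelines. Thresholds are
exclusive at the boundary: an E-value of exactly 1e-10 or a coverage of
exactly 95 does not qualify.

# Consensus NLRs

Annotation-derived NLR candidates are selected by case-insensitive
substring match of the functional description against "Disease",
"NBS-LRR" and "NB-ARC", deduplicated by gene id. The consensus keeps the
annotated gene models confirmed by ≥ 1 bp overlap with a de-novo locus
(the default of the standard interval-intersection tools); `minOverlap`
raises the bar, and strand is ignored by default because de-novo locus
strand calls need not match gene models. The catalogue is keyed on gene
models because downstream lists (orthogroups, trees) are gene-based.

# Orthogroup set algebra

The membership table maps each orthogroup to its gene ids per genome;
validity requires every gene to appear in exactly one group. Polyploid
panel members are split into subgenomes by user-supplied gene-id
patterns (`splitSubgenomes()`; a wheat-convention rule file for the
TraesCS/TRIDC id grammars ships in `inst/extdata/`), conserving gene
counts. `exclusiveSharedCount()` counts groups with members in *every*
genome of a set and *none* outside it; `upsetCounts()` enumerates all
realized combinations (they partition the groups, so counts sum to the
total); `singleCopyGroups()` requires exactly one gene per panel genome
and — in the default strict mode — zero genes outside the panel, since
"present once in each genome" is usually meant over the full split
panel.

# The simulators

Each simulator draws from its own named random stream derived from one
integer seed, so adding a simulator call never perturbs another's
output, and reruns are byte-identical.

* `simulateAlignments()` tiles chromosomes with ~40-kb alignments
  (±10 kb jitter, ~5-kb gaps) whose identities are the planted tract's
  target plus Gaussian noise (default sd 0.1 percentage points, clipped
  to [0, 100]), plus a configurable fraction of sub-filter decoys.
  Gaussian noise is a modelling choice — real identity dispersion is
  asymmetric near 100 % — adequate for targets ≤ 99.6 with sd 0.1.
* `simulateGenomePair()` emits actual sequences with per-tract
  substitution rates for end-to-end runs through an external aligner.
* `simulateProteinEvidence()` samples truth labels, realizes each as a
  qualified-hit combination from the classifier truth table, and draws
  metrics well inside the correct side of each threshold. UniMag
  negatives fail on both coverages together, keeping the four-flag
  truth table exact (mixed-coverage UniMag hits are the documented
  UNCLASSIFIED edge case, tested separately).
* `simulateNlrTracks()` plants gene models in evenly spaced slots with
  overlapping de-novo loci for a chosen fraction and decoys confined to
  inter-slot gaps, so the truth set is exact by construction.
* `simulateOrthogroupTable()` plants exact exclusive-combination counts
  and copy-number ranges.

What passing tests on these fixtures shows — and does not. The fixtures
exercise the algorithms' semantics exhaustively (run merging, rounding,
precedence, set algebra, overlap conventions) but are idealized: no
rearrangements, no repeat-induced many-to-many alignments, no
mis-assembly, uniform alignment tiling. Genome-scale block counts from
real assemblies depend on aligner behaviour on repeats and on assembly
quality, and are outside what desk-scale simulation can certify.

# Numerical choices and degenerate inputs

Medians are rounded half away from zero (a 1e-9 guard absorbs binary
representation error); base `round()`'s round-half-even would make
"identical median" merging depend on the parity of the last digit.
Empty alignment sets yield valid empty block sets, not errors; empty
bins have median NA; an empty block set has coverage 0 and undefined
mean length (NA). Alignment midpoints beyond the declared chromosome
length are an error (the length table contradicts the alignments), as
are inverted reference coordinates, duplicate protein ids, gene ids in
two orthogroups, and subgenome-split ids matching no (or several)
patterns.

# Problem sizes used in the test-suite

The shipped checks run at desk scale, chosen to finish in minutes while
still covering every code path: 500 random ≤ 20-bin instances against a
run-enumeration oracle; 100 seeded 100-Mb/20-bin recovery simulations
(tracts ≥ 3 bins, separations ≫ 2 rounding quanta, noise sd 0.1)
scoring per-chromosome Jaccard ≥ 0.9; 300 × 300 random interval pairs
across 100 seeds against quadratic scans; 10,000 simulated proteins;
all 63 subsets of a 6-genome panel; and a byte-level determinism rerun
of the full simulate → call → associate → summarize pipeline.

# Known limitations

* The haploblock caller assumes one reference coordinate system per
  call; translocations (e.g. a 4S–7S exchange) appear as blocks on the
  rearranged chromosomes rather than being modelled.
* Percent identity from PAF uses matches / alignment block length;
  cigar- or NM-based refinements are ignored.
* `identical_median` mode is sensitive to the rounding quantum by
  design; with noisy data prefer `threshold` mode or coarser rounding.
* The classifier consumes precomputed best hits and coverages; it does
  not recompute coverage from raw alignments.
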