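---
title: "Comparative plastome analysis with plastcomp: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastcomp: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcomp)
```

## The analysis in one paragraph

Land-plant chloroplast genomes (plastomes) are circular molecules of
roughly 120–170 kb with a conserved quadripartite organisation: a large and
a small single-copy region (LSC, SSC) separated by two identical inverted
repeats (IRa, IRb).  Comparative plastome studies characterise this
structure and its boundary shifts, catalogue dispersed repeats and
microsatellites (SSRs), count substitution and indel events between
genome pairs, screen for rapidly evolving regions usable as phylogenetic
markers, and map indel characters onto a phylogeny.  `plastcomp`
implements each of these stages as a tested, reusable function, and ships
a plastome-evolution simulator so that every stage can be validated
against planted ground truth without touching public databases.

## Coordinate conventions

All coordinates are 0-based, half-open, on the forward strand of the
stored sequence; GenBank's 1-based closed intervals are converted at the
file boundary.  Circular features may wrap the origin and are stored as
two intervals.  *Canonical orientation* rotates a genome so the LSC starts
at position 0 with region order LSC, IRb, SSC, IRa along the forward
strand, and chooses the strand on which the SSC sequence is
lexicographically no greater than its reverse complement.  The
lexicographic rule has no biological meaning; it is a deterministic
tie-break that makes the canonical form invariant to how the input was
rotated or flipped, which in turn makes cross-genome coordinates and
region extractions comparable.

## Quadripartite detection

`detect_quadripartite()` finds the maximal pair of disjoint, exactly
reverse-complementary segments of at least `min_ir` bp (default 10 kb —
large enough to skip dispersed repeats, far below real plastome IRs of
~25 kb).  Matching uses exact 25-mer seeding between the doubled sequence
and its reverse complement, followed by maximal extension, so IRs wrapping
the origin are found and detection cost is linear in practice.  Exact
matching is intentional: plastome IR copies are homogenised by concerted
evolution, and the simulator reproduces that; mismatch-tolerant IR
detection is out of scope.  Two equal-length maximal candidates raise an
ambiguity error rather than guessing.  The longer single-copy gap is
called LSC; IRb is the copy entered first when walking forward from the
LSC end.  Junctions JLB, JSB, JSA, JLA are reported as the coordinate of
the first base after each boundary.  Junction distances in
`junction_report()` are signed circular offsets from the junction to the
nearest gene end (positive downstream), with genes spanning a junction
flagged and their IR overlaps reported in bp.

## Dispersed repeats

`find_repeats()` reports maximal direct, reverse (reversed without
complementation) and palindromic (reverse-complemented) repeat pairs.  A
hit of length L may contain at most `min(max_mismatch, floor(0.10 * L))`
mismatches — both printed constraints of the classic repeat-finder
settings (minimum length 30, Hamming distance 3, identity ≥ 90%) hold
simultaneously.  A hit is *maximal* when extending either end would
violate the budget, run off the sequence, or hit an N: N columns act as
hard walls, never as matches or countable mismatches.  Hits contained in a
longer hit of the same type are suppressed; overlapping self-copies are
discarded (tandem arrays are SSR territory); hits longer than `max_len`
(default 5 kb) are dropped, which removes the genome-scale IR pair itself.
Completeness of the exact-match seeding is guaranteed by pigeonhole: any
qualifying hit contains an exact run of at least
`ceiling((min_len - max_mismatch) / (max_mismatch + 1))` bases.  Genome
scans run on the canonical sequence with IRa removed
(`strip_duplicate_ir()`), so each repeat is seen once.  Shared-repeat
bookkeeping keys a hit by (type, length, unordered pair of region names),
the natural reading of "identical lengths in homologous regions".

## SSRs

`find_ssrs()` reports maximal perfect tandem runs at the standard
plastome thresholds (mono ≥ 10 units, di ≥ 6, tri ≥ 5, tetra ≥ 4,
penta/hexa ≥ 3).  A run is reported only at its primitive period, loci
never overlap, and the scan wraps the origin on circular genomes.
Imperfect or compound SSRs are not merged — the tabulation counts simple
motifs.  Motif labels are strand-independent: among all cyclic rotations
of the unit and of its reverse complement, the lexicographically smallest
is the representative, giving labels such as `A/T` or `AAAAAG/CTTTTT`.
The genome report runs on the full two-IR sequence, so IR loci count once
per copy, and tags each locus with its functional location class and
partition.

## Substitution and indel events

`align_pair()` is a global Needleman–Wunsch aligner with affine gaps
(match +2, mismatch −3, gap open −8, gap extend −1; a gap of length g
costs 8 + g; N scores 0 against anything).  The implementation is
compiled; the test suite checks its scores against exhaustive enumeration
on tiny strings and against an established aligner under the same scoring.
The 20 kb input cap reflects the quadratic memory of full traceback;
whole genomes are compared region-wise instead: annotated regions (CDS,
introns, IGS, tRNA, rRNA) are matched across genomes by name, aligned
individually, and their events summed.  Region-wise alignment is also the
unit of analysis for marker screening, so the two views stay consistent.
An import path (`read_alignment_fasta()`) accepts externally produced
alignments.

Event counting follows the event convention, not the column convention:
one indel event is one maximal gap run regardless of length (in
multi-row alignments, one maximal run of columns sharing a gapped-row
pattern), and NS counts columns with two distinct non-N bases, typed by
unordered base pair.  Terminal gap runs are excluded by default in
`count_events()` because region boundaries are annotation artefacts; the
region-wise genome comparison keeps them, because there they represent
real length differences.  The S/I ratio is NS/ID, reported to two
decimals; it is undefined (error) at ID = 0.

The per-region variability statistic is the proportion of mutational
events, `(NS + ID) / L × 100`, with L the aligned length in columns.
`screen_markers()` keeps non-coding regions strictly above the threshold
(default 1.5%), sorted by decreasing variability; no multiple-testing
adjustment is applied because the screen is a fixed descriptive filter.
Partitioned divergence ratios average `(NS + ID)/L` per category (coding
: intron : IGS, or IR : LSC : SSC by the focal genome's partition at the
region midpoint) across partners and normalise to the first category,
reported to one decimal.

Multiple alignments for the variability table and for indel characters
are built by a star strategy: each genome is aligned pairwise to the
first, and the pairwise alignments are merged on reference coordinates
with insertions left-justified.  For the closely related, sparsely gapped
sequences this package targets, the star merge is effectively exact; it
is not a general progressive aligner and will degrade on deeply diverged
inputs.

## Indel characters and Fitch mapping

Every distinct maximal gap block of a region alignment becomes one binary
character (1 = carries the gap, 0 = carries sequence, NA = all-N across
the block).  Characters present in at least `min_taxa_present` taxa and
absent in at least two are flagged informative.  `fitch_assign()` roots
the tree at the outgroup, resolves polytomies arbitrarily (logged), and
computes the Fitch minimum change count with missing states treated as
compatible with either state.  One most-parsimonious reconstruction is
reported by the standard refinement that keeps the parent's state
whenever the downpass set allows it, with the root preferring the
outgroup's state; this delays changes away from the root (a
delayed-transformation-style tie-break) and is deterministic.  The change
count itself — the quantity validated exhaustively in the tests — is
identical for every most-parsimonious reconstruction.  Classes follow the
minimum-change rule: one change on an internal branch is a synapomorphy,
one change on a terminal branch an autapomorphy, two or more changes a
homoplasy.  Polarity is relative to the reconstructed root state: a
branch gaining the gap is a deletion (−), a branch losing it an insertion
(+), with ± when the root state is ambiguous.  Branch-support filtering
of synapomorphies is left to the user; the summary reports pure parsimony
classes.

## The simulator and what it does (and does not) emulate

`make_ancestor()` builds an annotated circular quadripartite genome.
Defaults are a realistic plastome: LSC 86,600 bp, SSC 18,280 bp, IR
26,090 bp, GC 0.373, a gene plan scaled to the partition sizes that
includes intron-containing genes (two of them with two introns), a 52-bp
and a 3-bp overlapping gene pair, an ndhF analogue 3 bp inside the SSC,
and a ycf1 analogue crossing the SSC|IRa junction by 1,068 bp.  Planted
SSR loci (A/T mononucleotides, one hexamer, one tetramer, one
sub-threshold run) and one planted repeat pair per type are recorded in a
truth table; their flanks are chosen non-extendable so recovery is exact
by construction.  The planted IR pair is made non-extendable at both
junctions, so detected coordinates equal planted coordinates exactly
rather than within a slack.

`evolve_along_tree()` evolves the ancestor along a newick tree.
Substitutions arrive per site at branch length × a partition multiplier
(default IR 1, LSC 3, SSC 3 — the IR evolves several-fold slower, the
single-copy regions at similar rates), with a transition bias of κ = 2
over a single-parameter substitution model; no selection or codon
structure is modelled, so *functional* categories (CDS vs intron vs IGS)
evolve at the same per-site rate and any CDS:intron:IGS contrast in
simulated data reflects positional composition only — the simulator
validates the machinery, not the biological claim that coding sequence is
constrained.  Indel events arrive at one third of the substitution rate
(matching plastome S/I ratios around 3), with lengths drawn from a
mixture dominated by 1-bp (0.45) and 5–6-bp (0.22) events and insertions
copying the adjacent upstream sequence with probability 0.8
(slipped-strand duplication).  Indels never split a planted SSR;
slippage at planted SSR loci changes the unit count by ±1 at a dedicated
rate (default 20 events per locus per unit branch length — replication
slippage runs orders of magnitude faster than point substitution).
Concerted evolution is on by default: the genome is evolved as a
LSC+IRb+SSC core and IRa is materialised as the mirror of IRb, so the two
copies are always identical; with `ir_concerted = FALSE` the IR copies
accumulate independent substitutions (indels remain mirrored — a
documented limitation).  Annotations and partition boundaries are lifted
over through every indel, and every event is recorded so that replaying
the truth table against the ancestor reproduces each tip byte-for-byte.

## Numerical and degenerate-input choices

* Ambiguity characters: N is accepted everywhere, excluded from GC
  denominators and substitution counting, and acts as a wall in repeat
  windows.
* Zero-length IGS between abutting or overlapping genes is omitted;
  overlaps are reported separately.
* Detection ambiguities (two maximal IR candidates, equal-length
  single-copy regions) raise errors instead of guessing.
* Ratios are rounded only at the reporting layer (S/I two decimals,
  partition ratios one decimal); full precision is kept internally.
* All randomness flows from explicit integer seeds; reports are
  byte-identical across reruns of one configuration.

## Problem sizes used in the checks

The validation suite runs entirely on synthetic data at desk scale:
structure detection on 200 genomes of 5–160 kb; repeat-finder equivalence
against a brute-force scan on sequences up to 2 kb; exhaustive
canonical-motif checks over all hexamers; Fitch-vs-exhaustive agreement
on 1,000 random trees of up to 8 taxa; and parameter recovery on 50
replicate pairs of ~13 kb genomes, where the estimated S/I ratio is
compared with the planted substitution-to-indel ratio, the IR is required
to be the slowest partition, and the 1-bp bin the modal indel class.  The
acceptance script (`scripts/acceptance.R`) recomputes the same quantities
at slightly reduced replicate counts plus a full-size (~157 kb) synthetic
plastome pass.

## Known limitations

* The star multiple alignment is reference-biased and unsuitable for
  deeply diverged taxa; import externally computed alignments for such
  data.
* IR detection requires exact copies; genomes with degenerate or lost IRs
  are reported as lacking quadripartite structure.
* The simulator's indels are at most 20 bp and never rearrange gene
  order; inversions, gene loss and IR expansion/contraction are not
  modelled.
* Whole-genome event totals depend on the region-wise decomposition;
  events spanning a region boundary can be counted in both flanking
  regions (or, with terminal-gap exclusion, in neither).  At the
  divergence levels targeted here this affects on the order of 2% of
  indel events.
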