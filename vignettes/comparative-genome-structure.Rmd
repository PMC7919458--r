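---
title: "Comparative genome structure inference and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genome structure inference and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package computes

`syntevo` re-implements, as one tested pipeline, the comparative
genome-structure analyses used to contrast closely related drosophilid
species: synteny blocks between assemblies, rearrangement counting and
inversion polarization on a species tree, double-cut-and-join (DCJ)
distances, branch assignment of transposable-element (TE) content,
tandem/dispersed duplication detection with enrichment statistics,
positional tRNA orthology with anticodon-shift calls, and conserved-intron
length comparison. Because real 150-Mb assemblies and the external
aligners used on them are out of scope, every inference module is
exercised on a forward genome evolver that plants known events along a
four-taxon-plus-outgroup phylogeny and logs them in a truth ledger, so the
pipeline's recall, branch accuracy and estimation error are measurable
quantities rather than hopes.

The default phylogeny is an ingroup trio (`dsim`, `dmau`, `dsec`) that
radiated 0.25 Myr ago, a reference lineage (`dmel`) that split 2.5 Myr ago
(leaving a 2.25-Myr ingroup stem branch), and an outgroup (`dyak`) on a
5-Myr edge. With the default substitution rate of 0.01 /bp/Myr this gives
roughly 5% sequence divergence between the reference and the trio and
7.5% to the outgroup, matching the few-percent divergence regime the
methods are designed for.

# The genome evolver

`simulate_ancestor()` builds a root genome: random background chromosomes
(default two arms of 2.5 Mb), a terminal pericentromeric heterochromatin
compartment, euchromatic protein-coding genes with exon/intron structure
and CDS bounds, tRNA genes in clusters (anticodons written into the
sequence at a fixed offset), satellite arrays of exact tandem monomers in
heterochromatin, and ancestral TE copies drawn from per-class family
consensus sequences with 4% per-copy substitution noise. TE length
distributions are log-normal per class with LTR elements longest and DNA
elements shortest.

`evolve_tree()` applies per-branch events — TE insertions, inversions,
tandem and dispersed duplications, satellite expansions/contractions,
tRNA duplications/deletions/anticodon point mutations, intron indels —
each drawn from a Poisson process with mean rate x branch Myr x genome
Mb, followed by Jukes–Cantor substitutions. Design choices that matter
downstream:

* **Coordinates** are 0-based half-open internally; GFF3 is emitted
  1-based closed, BED 0-based half-open.
* **Event ordering** within a branch is randomized from the branch's own
  RNG substream, and each event is interpreted against the current
  (post-previous-events) sequence. Every (branch, event type) has a named
  substream, so changing one rate leaves all other draws untouched and a
  fixed config + seed reproduces outputs byte-identically.
* **Heterochromatin** occupies the distal half of each arm by default and
  receives a 20x rearrangement-rate multiplier, which places >95% of
  inversions in heterochromatin under the default geometry.
* **Breakpoint hygiene**: inversion and duplication breakpoints are
  sampled so that no annotated feature is cut (features end up fully
  inside or fully outside), retried up to 50 times and otherwise skipped
  with a warning and excluded from the ledger. Substitutions never land
  within 5 bp of a planted breakpoint nor inside tRNA genes, so planted
  events remain recoverable and anticodon states are only changed by
  planted mutations.
* **Annotations ride along**: every edit updates the gene, tRNA, repeat
  and compartment tables and appends to an edit log, from which any
  interval can be lifted between the ancestral and derived frames.
  Features duplicated inside a copied segment are re-annotated for
  repeats but not for genes/tRNAs, mirroring the reality that only the
  ancestral-position annotation lifts over cleanly.
* The per-branch event rates are not reported by any study at this scale;
  the defaults are calibrated qualitatively so that branch-resolved TE
  content, inversion counts and duplication counts have the same *shape*
  as in real drosophilid comparisons (stem TE insertions 70% DNA-class,
  terminal insertions LTR-dominated; ~90% of rearrangements
  heterochromatic), and they are all configurable.

What the generator does **not** emulate: nucleotide-level TE decay,
within-species polymorphism, assembly error, or gene gain/loss outside
duplications. Passing recovery tests therefore demonstrates that the
inference machinery is correct on clean, fully-annotated genomes of a few
Mb; it does not certify performance on real assemblies, where annotation
noise and deeper repeat structure dominate.

# Synteny blocks from unique anchors

Anchors are maximal exact matches seeded by k-mers (default k = 21) whose
canonical form occurs exactly once in each genome, found by hash-table
scanning in C++. Repeats are anchor-free by construction — a satellite
array or a TE family with several copies has no unique k-mers — which
reproduces the "fails to align uniquely" semantics of whole-genome
aligners without a masking step.

Chaining is deliberately layered, because k-mer matches between
*different* copies of a repeat family are the dominant noise source:

1. a running-median filter on anchor diagonals removes clustered
   cross-matches that point far away;
2. a sequential scan with one-anchor lookahead builds collinear chains
   (gaps at most `max_gap` = 20 kb on both genomes), dropping short
   isolated contradictory anchors;
3. within each block, a weighted longest-increasing-subsequence keeps the
   maximum-anchored-bp collinear subchain (the spec of the chain
   objective), removing residual cross-matches;
4. blocks that a noise cluster split are re-merged when mutually
   collinear, and runs of thinly-anchored (<1 kb) blocks sandwiched
   between collinear neighbours are discarded;
5. spans shorter than `min_block` = 1 kb or with <200 anchored bp are
   dropped, and residual extent overlaps are clipped by a sweep.

The aligned fraction subtracts, from the block spans, the unbalanced
excess of every within-block gap (|ref gap − qry gap| when >50 bp): a
species-specific 5-kb TE insertion sits inside a block but is not aligned
sequence, and the headline "fraction failing to align uniquely" must see
it. Block identity is computed from exact anchors plus position-wise
comparison of equal-length gaps and global alignment of small unequal
gaps (both sides ≤2 kb); larger unbalanced gaps are unaligned, not
divergent. Interval projection interpolates linearly between anchors
inside a block and is exact on anchors.

# Rearrangements and polarization

Blocks numbered along the reference give, per chromosome, a signed
permutation of the query. Breakpoints are counted with the standard
sentinel convention (an adjacency `(a, b)` is intact iff `b = a + 1` in
signed terms). The "rearrangement count" between two genomes is reported
as this breakpoint count — the reproducible statistic closest to counting
aligner-derived rearrangements. Inversion calls are maximal runs of
sign-reversed, order-reversed blocks; nested structures resolvable only by
multi-taxon comparison are not decomposed.

Calls from different taxa are merged by ≥50% reciprocal overlap in the
reference frame; each merged event is scored in every taxon by projecting
its reference interval through that taxon's own map (derived when the
majority of the projected bases are inverted, missing when under half the
interval projects), and assigned a branch by Dollo parsimony: the unique
branch whose leaf set matches the derived taxa, with a polarity flip when
the *ancestral-like* taxa form the clade instead (an inversion shared by
trio and outgroup but not the reference maps to the reference terminal
branch). Events needing two origins stay unassigned. A call takes the
chromatin compartment of its midpoint; boundary-spanning calls are
conservatively heterochromatic.

The DCJ distance uses the adjacency-graph closed form
`d = N − (C + I/2)`; its correctness is checked against a breadth-first
search over genome space (a C++ oracle that knows nothing about adjacency
graphs) for every signed genome of up to six markers.

# TE branch assignment

Following the containment-plus-set-algebra procedure, the analysis is
restricted to euchromatic TEs (satellites excluded by default, toggle
available) and anchored on one focal ingroup taxon (`dmau`). An element
must lie 100% inside a single synteny block in each pairwise comparison;
it is shared with another taxon when its projection reciprocally overlaps
a same-class element by ≥50% of each element's length (the source method
states containment but no fraction; 50% reciprocal is robust to edge
erosion). Sharing patterns map to categories: both ingroup partners +
reference → complex-wide; both ingroup partners only → ingroup stem;
exactly one partner → pair-shared; none → taxon-specific. Patterns of
reference plus a single ingroup taxon imply ancestral presence with loss
and fold into complex-wide. Categories describe *detected* sharing, never
true absence. Composition tables report element counts and bp per class
within categories; exonic accounting intersects elements with the focal
taxon's exons.

# Duplications

A reference interval that fails to align uniquely but whose sequence has
two or more disjoint high-identity images in the query is a duplication
that arose in the query lineage. Candidates come from inter-anchor and
between-block reference gaps (≥50 bp, merged when <300 bp apart, because
post-duplication substitutions re-create unique k-mers and fragment one
event into several gaps), from reference intervals where flanking anchors
overlap (the signature of a *recent* duplication with no internal
divergence), and from query-side insertions matched back to the
reference. Images are k-mer hit clusters by diagonal, filtered by
coverage (≥50% of the candidate) and by a diagonal identity estimate
(≥0.90 — planted copies differ from their reference homolog by branch
substitutions only, while TE-family false images carry two copies' worth
of family noise and fall below it). Copies within 10 kb on one chromosome
are tandem, anything else dispersed; calls under 100 bp are dropped and
heterochromatic calls are excluded from the euchromatic analyses.

Per-taxon calls merge by ≥50% reciprocal overlap; events shared by the
whole ingroup and absent from the reference are stem candidates, minus
those also present in the outgroup (older, or a loss in the reference
lineage — flagged, never counted as stem gains), exactly the
ingroup-shared − outgroup-overlapping arithmetic. Overlap classes are
nested and maximal: `full_gene` (a transcript span inside the call) ⊃
`full_CDS` ⊃ `exonic` ⊃ `intergenic`. X enrichment is a one-sample
proportion test of X-linked calls against a null proportion.

# The statistics kernel

The proportion tests are continuity-corrected z tests; the correction and
the one- vs two-sided variant per headline result were chosen because
they reproduce the printed p-values exactly upon recomputation
(15/32 vs 0.158 two-sided → 4.7e-6; 62/86 vs 0.408 one-sided greater →
3.41e-9), and both variants are exposed as arguments. The exact binomial
(tail sums, minimum-likelihood two-sided) is available as the oracle and
agrees with the normal approximation to within 10% relative error in the
moderate-deviation regime (n ≥ 100, expected count ≥ 10). The paired t
test flags zero-variance difference vectors as degenerate (p reported as
1) rather than producing an infinite statistic. Rates are plain
count/Myr arithmetic with a years-per-event reciprocal.

# tRNA orthology

Each chromosome's tRNA genes become an isotype string (one amino-acid
letter per gene, lower-case for pseudogenes — display only, never
scored). `align_isotype_strings()` is the reference Needleman–Wunsch
(match +2, mismatch −1, gap −2, deterministic tie-breaking) whose scores
are verified against exhaustive enumeration. The multi-taxon merge aligns
every taxon to the reference and stacks columns on reference positions,
with three robustness layers developed against the truth ledger:

* the pairwise scorer used for merging is anticodon-aware: a mismatch is
  tolerable only when the two genes' anticodons differ by at most one
  base (the signature of a genuine shift), otherwise gaps win — without
  this, adjacent copy-number changes in different taxa stack unrelated
  genes;
* gap placement inside runs of identical isotype letters is canonicalized
  (members occupy the leftmost reference positions, surplus genes become
  insertions), otherwise equal-scoring gap choices drift between taxa and
  split ortholog columns;
* a member whose isotype differs from the reference member's *and* whose
  anticodon is more than one base away is split into its own column as
  misorthology.

Copy gains and losses are polarized against the outgroup by the same
Dollo rule as inversions (with the polarity flip deciding gain vs loss);
anticodon shifts are isoacceptor when all members share the isotype and
alloacceptor otherwise, with the outgroup fixing the ancestral state.
Cluster boundaries fall at inter-gene gaps >5 kb; strand is recorded and
flank agreement with the synteny projection (±1 kb) flags low-confidence
columns when maps are supplied. Shifts produced by two planted mutations
on one gene lineage are genuinely multi-state and excluded from accuracy
scoring as ambiguous.

# Conserved introns

Ortholog genes (shared ids from the simulator; a supplied ortholog table
for real data) are compared across the four non-outgroup taxa: one
isoform per gene, equal exon counts required, and an intron kept when
both flanking exons differ by ≤10% in length between each taxon and the
reference (`|a − b| / max(a, b)`, the symmetric reading of the published
rule; an all-pairs mode is available). An intron is complex when it
overlaps ≥1 bp of TE or satellite annotation, simple otherwise; for a
two-species comparison an intron counts as complex when complex in either
species (configurable to both). Length comparisons are two-sided paired t
tests on per-intron differences, optionally restricted by class and by
the reference-frame compartment of the intron midpoint.

# Problem sizes and numerical choices

The recovery analyses run at the generator's default scale — five genomes
of 5 Mb (two chromosomes each), seven pairwise maps — which the test
suite and the acceptance script build once and reuse; the dedicated
intron-effect and anticodon-shift scenarios use 2.4 Mb and 0.6 Mb
genomes, sized so that the conserved-intron set exceeds 500 introns and
the planted shift count supports an accuracy estimate. k-mer size 21 is
large enough that random 21-mers essentially never repeat in a 5-Mb
genome and small enough to survive 5–7.5% divergence; `max_gap` 20 kb
spans planted TE insertions without splitting blocks; the anchor
weighted-chain and the identity computations are exact, not heuristic, at
these scales. Ties everywhere (chain scoring, alignment traceback,
category assignment) are broken deterministically and documented at the
function level.

# Known limitations

* Blocks, and therefore breakpoint counts, depend on `max_gap` and
  `min_block` exactly as aligner-derived rearrangement counts depend on
  the aligner's weight parameters; the absolute counts from real ~180-Mb
  assemblies are not reproducible at desk scale and are not claimed.
* Duplication detection sees copy-number ≥2 images in unique sequence; it
  does not call duplications nested inside repeat families, and
  read-depth evidence is out of scope.
* The anchor-uniqueness definition of "aligns uniquely" is an analog of,
  not a re-implementation of, external aligners' behaviour.
* Dollo polarization assumes no regain; recurrent events at one locus on
  different branches are flagged ambiguous rather than resolved.
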