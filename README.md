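# syntevo

Comparative genome-structure analysis for closely related species, with a
built-in forward genome evolver that makes every inference step testable
against planted truth.

## The problem

When near-chromosome-level assemblies exist for a clade of closely related
species — an ingroup trio that radiated ~0.25 Myr ago, a reference species
that split ~2.5 Myr ago, and an outgroup — the interesting biology lives in
genome *structure*: which inversions, transposable-element (TE) insertions,
tandem duplications, satellite expansions, tRNA cluster changes and intron
indels happened on which branch of the species tree. `syntevo` implements
that comparative toolkit end to end:

* **Synteny**: orientation-aware collinear blocks from k-mers that occur
  exactly once in each genome (repeats are anchor-free by construction, so
  "fails to align uniquely" falls out of the block structure), plus
  alignment summaries and interval projection between genomes.
* **Rearrangements**: signed block permutations, breakpoint counts,
  inversion calls, and the double-cut-and-join (DCJ) distance
  `d = N − (C + I/2)` from the adjacency graph, verified against a
  breadth-first-search oracle over genome space.
* **Polarization**: Dollo parsimony on a presence matrix with outgroup
  evidence — each derived event is assigned the unique branch consistent
  with a single origin, including the polarity flip that maps events shared
  by ingroup *and* outgroup onto the reference lineage.
* **TE branch assignment**: strict syntenic containment plus pairwise set
  algebra over shared elements (complex-wide / ingroup-stem / pair-shared /
  species-specific), class composition and exonic base accounting.
* **Duplications**: tandem and dispersed calls from multi-image k-mer
  evidence, ingroup-shared minus outgroup-overlapping stem counts,
  nested gene-overlap classes (`full_gene` ⊃ `full_CDS` ⊃ `exonic`),
  X-chromosome enrichment proportion tests and per-Myr fixation rates.
* **tRNAs**: positional orthology via isotype-string alignment across taxa,
  copy gains/losses polarized on the tree, and anticodon shifts classified
  isoacceptor (same amino acid) vs alloacceptor (different amino acid).
* **Introns**: conserved orthologous introns (equal exon counts, flanking
  exons within 10% length), complex vs simple by repeat content, paired t
  tests of length differences.
* **Statistics kernel**: continuity-corrected proportion tests (one- and
  two-sample), exact binomial oracle, paired t, and rate arithmetic.

Real assemblies are gigabase-scale and annotated with external tools; here
the data come from `simulate_complex()`, a genome evolver that plants every
event class along the tree under named RNG substreams and writes a truth
ledger, so recall, branch accuracy and estimation error are measured, not
assumed.

## Worked example

```r
library(syntevo)

cfg <- evolution_config(seed = 3L, chrom_lengths = c(chrX = 4e5, chr2 = 4e5),
                        n_genes = 40L, n_trnas = 20L, n_trna_clusters = 4L,
                        n_satellites = 4L, ancestral_te_count = 30L)
sim <- simulate_complex(cfg)
map <- build_map(sim$genomes$dmel, sim$genomes$dsim)
map
#> alignment_map: 39 blocks, 14427 anchors (k = 21 )
#>   aligned fraction: ref 0.858, qry 0.865

summarize_alignment(map)$mean_block_identity
#> [1] 0.9168616
```

About 14% of the simulated ingroup genome fails to align uniquely to the
reference (planted TEs, satellites and duplications), and the aligned
fraction carries the ~5% substitution divergence that 5 Myr of separation
at the default rate produces. Inversions polarize onto branches:

```r
ia <- inversion_analysis(
  lapply(sim$genomes[c("dsim","dmau","dsec","dyak")],
         function(g) build_map(sim$genomes$dmel, g)),
  sim$phylogeny, compartments = sim$genomes$dmel$compartments)
table(ia$events$branch)
#> dmau dmel dyak stem
#>    1    5    4    4
```

and the statistics kernel reproduces the published enrichment arithmetic
from its printed inputs:

```r
prop_test_one_sample(43, 86, 0.158)
#> Proportion test: one-sample (two_sided, continuity-corrected)
#>   x/n = 43/86 = 0.5000  vs  p0 = 0.1580
#>   z = 8.5476, p = 1.257e-17

duplication_rate(32, 2.5)
#> $rate
#> [1] 12.8
#> $years_per_gene
#> [1] 78125
```

The `analysis/` directory holds the full workflow as numbered scripts
(`01_simulate.R` … `08_report.R`); each reads the previous step's output
under `results/` and writes TSV/PAF/FASTA artifacts plus a final summary
table.

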