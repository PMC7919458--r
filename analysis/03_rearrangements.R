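#!/usr/bin/env Rscript
# Genome rearrangements: signed block permutations per taxon, breakpoint
# counts, inversion calls polarized onto tree branches by Dollo parsimony
# with outgroup evidence, chromatin compartment classification, and
# pairwise DCJ distances between the block orders.

library(syntevo)

sim <- readRDS("results/sim.rds")
maps <- readRDS("results/maps.rds")$maps
phy <- sim$phylogeny
dir.create("results/rearrangements", showWarnings = FALSE, recursive = TRUE)

# breakpoint counts per taxon vs the reference
bp <- data.table::rbindlist(lapply(names(maps), function(t) {
  p <- blocks_to_permutation(maps[[t]])
  data.table::data.table(taxon = t,
                         n_blocks = sum(lengths(p)),
                         breakpoints = count_breakpoints(p))
}))
write_tsv(bp, "results/rearrangements/breakpoints.tsv")
print(bp)

# inversion events with branch assignment and compartments
ia <- inversion_analysis(maps, phy, compartments = sim$genomes$dmel$compartments)
write_tsv(ia$events, "results/rearrangements/inversions.tsv")
message(nrow(ia$events), " inversion events; ",
        round(100 * mean(ia$events$compartment == "het")),
        "% heterochromatic; branch distribution:")
print(table(ia$events$branch, useNA = "ifany"))

# DCJ distances between the trio's block orders (markers = shared blocks
# of each pair's permutations, linear chromosomes)
dcj <- list()
taxa <- names(maps)
for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
  if (i >= j) next
  pa <- blocks_to_permutation(maps[[taxa[i]]])
  pb <- blocks_to_permutation(maps[[taxa[j]]])
  common <- intersect(names(pa), names(pb))
  d <- 0L
  for (ch in common) {
    shared <- intersect(abs(pa[[ch]]), abs(pb[[ch]]))
    if (length(shared) < 2) next
    relab <- function(v) {
      v <- v[abs(v) %in% shared]
      sign(v) * match(abs(v), sort(shared))
    }
    d <- d + dcj_distance(list(relab(pa[[ch]])), list(relab(pb[[ch]])), "linear")
  }
  dcj[[length(dcj) + 1L]] <- data.table::data.table(
    taxonA = taxa[i], taxonB = taxa[j], dcj = d)
}
dcj <- data.table::rbindlist(dcj)
write_tsv(dcj, "results/rearrangements/dcj_distances.tsv")
print(dcj)
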