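#!/usr/bin/env Rscript
# Tandem and dispersed duplications: detection from the alignment maps,
# polarization onto branches (ingroup-shared minus outgroup-overlapping =
# stem), gene-overlap classification, X enrichment, and per-Myr fixation
# rates on the stem branch.

library(syntevo)

sim <- readRDS("results/sim.rds")
maps <- readRDS("results/maps.rds")$maps
phy <- sim$phylogeny
g <- sim$genomes
dir.create("results/duplications", showWarnings = FALSE, recursive = TRUE)

calls <- lapply(maps[phy$ingroup], function(m)
  filter_euchromatic(detect_duplications(m), g$dmel$compartments))
ogc <- filter_euchromatic(detect_duplications(maps[[phy$outgroup]]),
                          g$dmel$compartments)
pol <- polarize_duplications(calls, ogc, phy)
events <- classify_overlap(pol$events, g$dmel$genes, g$dmel$exons)
write_tsv(events, "results/duplications/events.tsv")

message(sprintf("ingroup-shared %d, outgroup-overlapping %d, stem %d",
                pol$n_ingroup_shared, pol$n_outgroup_overlap, pol$n_stem))
message("overlap classes of stem events:")
stem <- events[events$status == "stem", ]
print(table(stem$overlap_class))

if (nrow(stem) > 0) {
  xe <- x_enrichment(stem, null_prop = 0.158)
  message(sprintf("X-linked stem duplications: %d/%d, p = %.3g",
                  xe$x_count, xe$n, xe$test$p_value))
  stem_myr <- phy$branches[["stem"]]
  full <- sum(stem$overlap_class %in% c("full_CDS", "full_gene"))
  r <- duplication_rate(full, stem_myr)
  message(sprintf("full-CDS duplications: %d over %.2f Myr = %.2f/Myr (one per %.0f yr)",
                  full, stem_myr, r$rate,
                  if (full > 0) r$years_per_gene else NA))
  write_tsv(data.table::data.table(
    n_ingroup_shared = pol$n_ingroup_shared,
    n_outgroup_overlap = pol$n_outgroup_overlap,
    n_stem = pol$n_stem, x_count = xe$x_count,
    p_x = xe$test$p_value, full_cds = full,
    rate_per_myr = r$rate), "results/duplications/summary.tsv")
}
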