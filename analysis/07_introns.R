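#!/usr/bin/env Rscript
# Conserved orthologous introns across the four mel-complex taxa, classed
# complex (TE/satellite-containing) vs simple, with paired length
# comparisons of the reference against each ingroup taxon, split by class
# and chromatin compartment.

library(syntevo)

sim <- readRDS("results/sim.rds")
g <- sim$genomes
dir.create("results/introns", showWarnings = FALSE, recursive = TRUE)

four <- c("dmel", "dsim", "dmau", "dsec")
ci <- match_conserved_introns(g[four], taxa = four, ref_taxon = "dmel")
ci <- data.table::rbindlist(lapply(four, function(t)
  classify_intron(ci[ci$taxon == t, ], g[[t]]$repeats)))
write_tsv(ci, "results/introns/conserved_introns.tsv")
message(nrow(ci) / length(four), " conserved introns in ",
        length(unique(ci$gene_id)), " ortholog genes")

rows <- list()
for (t in c("dsim", "dmau", "dsec")) {
  for (cl in c("all", "complex", "simple")) {
    for (comp in c("all", "eu", "het")) {
      cmp <- compare_intron_lengths(ci, "dmel", t, class = cl,
                                    compartment = comp,
                                    compartments = g$dmel$compartments)
      if (is.null(cmp)) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        pair = paste0("dmel-", t), class = cl, compartment = comp,
        n = cmp$n, mean_diff = cmp$mean_diff, t_stat = cmp$test$t,
        p_value = cmp$test$p_value, degenerate = cmp$test$degenerate)
    }
  }
}
out <- data.table::rbindlist(rows)
write_tsv(out, "results/introns/length_comparisons.tsv")
print(out[out$compartment == "all", ])
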