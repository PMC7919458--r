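#!/usr/bin/env Rscript
# Aggregate the module outputs into one summary table, and recompute the
# headline comparative statistics that the pipeline's statistics kernel is
# calibrated against: duplication fixation rates on a 2.5-Myr stem branch
# and the X-enrichment proportion tests for the published duplicate counts
# (32 full-CDS and 62 exonic duplicates; 43/86 and 15/32 X-linked against
# an X-linked gene proportion of 0.158; 62/86 exonic against the 0.408
# polymorphic proportion; 113 rearrangements over 2 x 0.25 Myr).

library(syntevo)

rows <- list()
add <- function(section, metric, value)
  rows[[length(rows) + 1L]] <<- data.table::data.table(
    section = section, metric = metric, value = value)

grab <- function(path) if (file.exists(path)) read_tsv(path) else NULL

s <- grab("results/synteny/alignment_summary.tsv")
if (!is.null(s)) {
  add("alignment", "mean_identity_dmel_dsim",
      s$mean_block_identity[s$taxon == "dsim"])
  add("alignment", "unaligned_fraction_dsim",
      1 - s$qry_aligned_fraction[s$taxon == "dsim"])
}
inv <- grab("results/rearrangements/inversions.tsv")
if (!is.null(inv)) {
  add("rearrangements", "n_inversion_events", nrow(inv))
  add("rearrangements", "het_fraction", mean(inv$compartment == "het"))
}
dup <- grab("results/duplications/summary.tsv")
if (!is.null(dup)) {
  add("duplications", "n_stem", dup$n_stem)
  add("duplications", "stem_rate_per_myr", dup$rate_per_myr)
}
sh <- grab("results/trna/anticodon_shifts.tsv")
if (!is.null(sh)) add("trna", "n_anticodon_shifts", nrow(sh))
ic <- grab("results/introns/length_comparisons.tsv")
if (!is.null(ic)) add("introns", "n_conserved",
                      ic$n[ic$class == "all" & ic$compartment == "all"][1])

# published-count arithmetic, recomputed
add("published", "rate_full_cds_per_myr", duplication_rate(32, 2.5)$rate)
add("published", "years_per_new_gene", duplication_rate(32, 2.5)$years_per_gene)
add("published", "rate_exonic_per_myr", duplication_rate(62, 2.5)$rate)
add("published", "rearrangement_rate_within_complex", rate_per_myr(113, 0.5)$rate)
add("published", "p_x_full_cds",
    prop_test_one_sample(15, 32, 0.158)$p_value)
add("published", "p_x_tandem",
    prop_test_one_sample(43, 86, 0.158)$p_value)
add("published", "p_exonic_fixed_vs_polymorphic",
    prop_test_one_sample(62, 86, 0.408, "greater")$p_value)

out <- data.table::rbindlist(rows)
write_tsv(out, "results/summary.tsv")
print(out)
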