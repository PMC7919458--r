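#' Configuration of the forward genome evolver
#'
#' Bundles every tunable of the ancestral-genome generator and the per-branch
#' event process. All event rates are in events per Mb per Myr and may be a
#' single number (applied to every branch) or a named vector over branches
#' (`dsim`, `dmau`, `dsec`, `stem`, `dmel`, `dyak` for the default
#' phylogeny). Identical config + seed reproduces outputs byte-identically.
#'
#' Defaults model a desk-scale cartoon of a drosophilid species complex:
#' two ~2.5-Mb chromosomes (an X and an autosome) with the distal half of
#' each arm pericentromeric heterochromatin, euchromatic genes and tRNA
#' clusters, heterochromatic satellite arrays, and TE families whose class
#' mixture differs between the ingroup stem (DNA-transposon dominated) and
#' the terminal branches (LTR dominated).
#'
#' @param seed Integer master seed; every random draw derives from it through
#'   named substreams, so changing one rate does not perturb other draws.
#' @param chrom_lengths Named integer vector of background chromosome
#'   lengths (before ancestral insertions).
#' @param het_fraction Fraction of each chromosome occupied by the terminal
#'   (pericentromeric) heterochromatin segment.
#' @param het_multiplier Rearrangement rate multiplier of heterochromatin
#'   relative to euchromatin; with the default geometry a multiplier of 20
#'   places >95 percent of inversions in heterochromatin.
#' @param n_genes,exons_per_gene,exon_length_range,intron_length_range
#'   Euchromatic gene complement of the ancestor.
#' @param n_trnas,n_trna_clusters tRNA gene complement, placed in clusters.
#' @param n_satellites,satellite_monomer_range,satellite_copy_range
#'   Heterochromatic satellite arrays of the ancestor.
#' @param ancestral_te_count,ancestral_te_mix,ancestral_te_exonic,ancestral_te_intronic
#'   Ancestral TE insertions: count, class mixture (`DNA`, `LTR`, `nonLTR`),
#'   and the fraction targeted into exons / introns.
#' @param te_families_per_class,te_copy_noise Number of TE families per class
#'   and the per-copy substitution noise applied to family consensus
#'   sequences when a copy is planted.
#' @param te_rate,te_class_mix,te_exonic,te_intronic TE insertion process per
#'   branch: rate, class mixture (a list with entries `stem` and `default`),
#'   and exon/intron targeting fractions for branch insertions.
#' @param te_length_meanlog,te_length_sdlog Log-normal TE length parameters
#'   per class (LTR longest, DNA shortest).
#' @param inversion_rate,inversion_length_range Inversion process; lengths
#'   are drawn log-uniformly.
#' @param tandem_dup_rate,tandem_dup_meanlog,tandem_dup_sdlog,tandem_extra_copy_prob
#'   Euchromatic tandem duplications (a third copy is added with the stated
#'   probability).
#' @param dispersed_dup_rate Euchromatic dispersed duplications.
#' @param satellite_change_rate Satellite array expansion/contraction events.
#' @param trna_dup_rate,trna_del_rate,trna_anticodon_rate tRNA cluster
#'   events; anticodon mutations are single-base changes of the anticodon.
#' @param trna_allo_prob Probability that a planted anticodon mutation is an
#'   alloacceptor (amino-acid changing) shift rather than an isoacceptor one.
#' @param intron_indel_rate,intron_indel_mean,intron_indel_max,intron_indel_ins_prob
#'   Intron indel process: rate, geometric-like mean length, length cap,
#'   and the probability that an indel is an insertion (0.5 = unbiased;
#'   per-branch values allow planting directional intron length effects).
#' @param sub_rate Substitutions per bp per Myr (Jukes-Cantor), applied after
#'   the structural events of each branch, never within +/-5 bp of a planted
#'   breakpoint and never inside tRNA genes.
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(
  seed = 1L,
  chrom_lengths = c(chrX = 2.5e6, chr2 = 2.5e6),
  het_fraction = 0.5,
  het_multiplier = 20,
  n_genes = 160L,
  exons_per_gene = c(4L, 6L),
  exon_length_range = c(90L, 450L),
  intron_length_range = c(61L, 800L),
  n_trnas = 40L,
  n_trna_clusters = 8L,
  n_satellites = 10L,
  satellite_monomer_range = c(90L, 500L),
  satellite_copy_range = c(20L, 60L),
  ancestral_te_count = 150L,
  ancestral_te_mix = c(DNA = 0.30, LTR = 0.18, nonLTR = 0.52),
  ancestral_te_exonic = 0.5,
  ancestral_te_intronic = 0.2,
  te_families_per_class = 6L,
  te_copy_noise = 0.04,
  te_rate = c(dsim = 24, dmau = 24, dsec = 24, stem = 8, dmel = 8, dyak = 4),
  te_class_mix = list(
    stem = c(DNA = 0.70, LTR = 0.10, nonLTR = 0.20),
    default = c(DNA = 0.14, LTR = 0.52, nonLTR = 0.34)
  ),
  te_exonic = 0.10,
  te_intronic = 0.25,
  te_length_meanlog = c(DNA = log(600), LTR = log(4000), nonLTR = log(2000)),
  te_length_sdlog = c(DNA = 0.5, LTR = 0.4, nonLTR = 0.5),
  inversion_rate = 1.2,
  inversion_length_range = c(2e3, 2e5),
  tandem_dup_rate = 2.5,
  tandem_dup_meanlog = log(1500),
  tandem_dup_sdlog = 0.6,
  tandem_extra_copy_prob = 0.1,
  dispersed_dup_rate = 0.6,
  satellite_change_rate = 1.0,
  trna_dup_rate = 0.2,
  trna_del_rate = 0.15,
  trna_anticodon_rate = 0.1,
  trna_allo_prob = 0.75,
  intron_indel_rate = 4,
  intron_indel_mean = 10,
  intron_indel_max = 200,
  intron_indel_ins_prob = 0.5,
  sub_rate = 0.01
) {
  cfg <- as.list(environment())
  rates <- c("te_rate", "inversion_rate", "tandem_dup_rate", "dispersed_dup_rate",
             "satellite_change_rate", "trna_dup_rate", "trna_del_rate",
             "trna_anticodon_rate", "intron_indel_rate", "sub_rate")
  for (r in rates) {
    v <- cfg[[r]]
    if (!is.numeric(v) || any(v < 0)) stop("'", r, "' must be non-negative")
  }
  if (cfg$het_fraction < 0 || cfg$het_fraction >= 1)
    stop("'het_fraction' must lie in [0, 1)")
  if (any(chrom_lengths <= 0) || is.null(names(chrom_lengths)))
    stop("'chrom_lengths' must be a named vector of positive lengths")
  stopifnot(abs(sum(ancestral_te_mix) - 1) < 1e-6)
  for (m in cfg$te_class_mix) stopifnot(abs(sum(m) - 1) < 1e-6)
  structure(cfg, class = "evolution_config")
}

# Resolve a possibly per-branch rate to the scalar for one branch.
branch_rate <- function(rate, branch) {
  if (length(rate) == 1L && is.null(names(rate))) return(unname(rate))
  if (!is.null(names(rate)) && branch %in% names(rate)) return(unname(rate[[branch]]))
  if (length(rate) == 1L) return(unname(rate))
  stop("no rate entry for branch '", branch, "'")
}

# Deterministic seed for a named substream, derived from the master seed.
# Plain polynomial string hash, folded into the 32-bit signed range.
substream_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483563
  as.integer((h + as.numeric(seed) * 7919) %% 2147483563) + 1L
}

#' @export
print.evolution_config <- function(x, ...) {
  cat("evolution_config: seed", x$seed, "|",
      length(x$chrom_lengths), "chromosomes,",
      sprintf("%.1f Mb total |", sum(x$chrom_lengths) / 1e6),
      "het fraction", x$het_fraction, "\n")
  invisible(x)
}
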