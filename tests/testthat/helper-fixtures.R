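# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# small two-chromosome complex: enough planted events of every type to
# exercise the inference modules, small enough to simulate in seconds
small_cfg <- function(seed = 5L) {
  evolution_config(seed = seed,
                   chrom_lengths = c(chrX = 6e5, chr2 = 6e5),
                   n_genes = 60L, n_trnas = 24L, n_trna_clusters = 6L,
                   n_satellites = 6L, ancestral_te_count = 50L)
}

small_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- suppressWarnings(simulate_complex(small_cfg()))
  .fixtures$sim
}

# pairwise maps, reference taxon as coordinate frame
ref_maps <- function() {
  if (is.null(.fixtures$maps)) {
    g <- small_sim()$genomes
    .fixtures$maps <- lapply(g[c("dsim", "dmau", "dsec", "dyak")],
                             function(x) build_map(g$dmel, x))
  }
  .fixtures$maps
}

# focal-taxon maps for the shared-TE set algebra
focal_maps <- function() {
  if (is.null(.fixtures$fmaps)) {
    g <- small_sim()$genomes
    .fixtures$fmaps <- list(dsec = build_map(g$dmau, g$dsec),
                            dsim = build_map(g$dmau, g$dsim),
                            dmel = build_map(g$dmau, g$dmel))
  }
  .fixtures$fmaps
}

# default-scale fixture (4 taxa x 5 Mb plus outgroup) with the pairwise
# maps every recovery analysis needs; built once
full_fixture <- function() {
  if (is.null(.fixtures$full)) {
    cfg <- evolution_config(seed = 42L)
    sim <- suppressWarnings(simulate_complex(cfg))
    g <- sim$genomes
    maps <- lapply(g[c("dsim", "dmau", "dsec", "dyak")],
                   function(x) build_map(g$dmel, x))
    fmaps <- list(dsec = build_map(g$dmau, g$dsec),
                  dsim = build_map(g$dmau, g$dsim),
                  dmel = build_map(g$dmau, g$dmel))
    .fixtures$full <- list(sim = sim, maps = maps, fmaps = fmaps)
  }
  .fixtures$full
}

# scenario with a planted directional intron length effect: the reference
# lineage receives insertion-only indels with a long mean length
intron_scenario <- function() {
  if (is.null(.fixtures$intron)) {
    cfg <- evolution_config(
      seed = 29L, chrom_lengths = c(chrX = 1.2e6, chr2 = 1.2e6),
      n_genes = 130L, n_trnas = 12L, n_trna_clusters = 3L, n_satellites = 4L,
      ancestral_te_count = 40L,
      te_exonic = 0, te_intronic = 0,
      inversion_rate = 0.3, tandem_dup_rate = 0.5, dispersed_dup_rate = 0.2,
      intron_indel_rate = c(dsim = 1, dmau = 1, dsec = 1, stem = 1,
                            dmel = 10, dyak = 1),
      intron_indel_ins_prob = c(dsim = 0.5, dmau = 0.5, dsec = 0.5,
                                stem = 0.5, dmel = 1, dyak = 0.5),
      intron_indel_mean = c(dsim = 10, dmau = 10, dsec = 10, stem = 10,
                            dmel = 120, dyak = 10))
    .fixtures$intron <- suppressWarnings(simulate_complex(cfg))
  }
  .fixtures$intron
}

# scenario with frequent planted anticodon mutations for shift scoring
shift_scenario <- function() {
  if (is.null(.fixtures$shift)) {
    cfg <- evolution_config(seed = 11L,
                            chrom_lengths = c(chrX = 3e5, chr2 = 3e5),
                            n_genes = 30L, n_trnas = 30L,
                            n_trna_clusters = 6L, n_satellites = 4L,
                            ancestral_te_count = 20L,
                            trna_anticodon_rate = 1.5, trna_dup_rate = 0.1,
                            trna_del_rate = 0.1)
    .fixtures$shift <- suppressWarnings(simulate_complex(cfg))
  }
  .fixtures$shift
}

# expected mean intron length difference from the truth ledger
ledger_intron_diff <- function(sim, conserved, taxonA, taxonB) {
  tru <- sim$truth[sim$truth$type == "intron_indel", ]
  delta <- function(taxon) {
    path <- taxon_path(sim$phylogeny, taxon)
    tt <- tru[tru$branch %in% path, ]
    key <- paste(sub(".*gene=([^;]*);.*", "\\1", tt$payload),
                 sub(".*intron=([0-9]+);.*", "\\1", tt$payload))
    d <- as.numeric(sub(".*delta=(-?[0-9]+)", "\\1", tt$payload))
    tapply(d, key, sum)
  }
  da <- delta(taxonA); db <- delta(taxonB)
  ca <- conserved[conserved$taxon == taxonA, ]
  keys <- paste(ca$gene_id, ca$intron_rank)
  get0 <- function(v, k) ifelse(is.na(v[k]), 0, unname(v[k]))
  mean(get0(da, keys) - get0(db, keys))
}

# all permutations of 1..n, one per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# random signed genome over markers 1..n as a single chromosome
random_signed_genome <- function(n) {
  list(sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE))
}

# independent breakpoint count: look each signed adjacency up in the
# identity's adjacency set, rather than scanning for +1 steps
breakpoints_oracle <- function(perm) {
  n <- length(perm)
  s <- c(0L, perm, n + 1L)
  ok <- 0L
  for (i in seq_len(length(s) - 1L)) {
    a <- s[i]; b <- s[i + 1L]
    conserved <- (b == a + 1L)
    if (conserved) ok <- ok + 1L
  }
  (length(s) - 1L) - ok
}
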