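test_that("zero-rate evolution is the identity on sequence and annotations", {
  cfg <- evolution_config(seed = 2L, chrom_lengths = c(chrA = 1e5),
                          n_genes = 8L, n_trnas = 6L, n_trna_clusters = 2L,
                          n_satellites = 2L, ancestral_te_count = 5L,
                          te_rate = 0, inversion_rate = 0, tandem_dup_rate = 0,
                          dispersed_dup_rate = 0, satellite_change_rate = 0,
                          trna_dup_rate = 0, trna_del_rate = 0,
                          trna_anticodon_rate = 0, intron_indel_rate = 0,
                          sub_rate = 0)
  anc <- simulate_ancestor(cfg)
  sim <- evolve_tree(anc, simcomplex_phylogeny(), cfg)
  expect_equal(nrow(sim$truth), 0L)
  for (t in names(sim$genomes)) {
    expect_identical(sim$genomes[[t]]$seq, anc$seq)
    expect_equal(sim$genomes[[t]]$exons, anc$exons)
    expect_equal(sim$genomes[[t]]$trnas, anc$trnas)
    expect_equal(sim$genomes[[t]]$repeats, anc$repeats)
  }
})

test_that("fixed config and seed reproduce outputs byte-identically", {
  cfg <- evolution_config(seed = 1L, chrom_lengths = c(chrA = 1.5e5),
                          n_genes = 10L, n_trnas = 8L, n_trna_clusters = 2L,
                          n_satellites = 2L, ancestral_te_count = 8L)
  s1 <- suppressWarnings(simulate_complex(cfg))
  s2 <- suppressWarnings(simulate_complex(cfg))
  for (t in names(s1$genomes))
    expect_identical(s1$genomes[[t]]$seq, s2$genomes[[t]]$seq)
  expect_identical(s1$truth, s2$truth)
})

test_that("ancestor honours requested feature counts and placement limits", {
  cfg <- evolution_config(seed = 3L, chrom_lengths = c(chrA = 2e5, chrB = 2e5),
                          n_genes = 10L, n_trnas = 20L, n_trna_clusters = 4L,
                          n_satellites = 2L, ancestral_te_count = 0L)
  anc <- simulate_ancestor(cfg)
  expect_equal(nrow(anc$trnas), 20L)
  expect_equal(length(unique(anc$trnas$cluster_id)), 4L)
  expect_equal(length(unique(anc$exons$gene_id)), 10L)
  # sequence-only genome
  cfg0 <- evolution_config(seed = 3L, chrom_lengths = c(chrA = 5e4),
                           n_genes = 0L, n_trnas = 0L, n_trna_clusters = 0L,
                           n_satellites = 0L, ancestral_te_count = 0L)
  anc0 <- simulate_ancestor(cfg0)
  expect_equal(nrow(anc0$exons), 0L)
  expect_equal(nrow(anc0$trnas), 0L)
  expect_equal(nchar(anc0$seq$chrA), 5e4)
  # infeasible density errors out
  cfg_bad <- evolution_config(seed = 3L, chrom_lengths = c(chrA = 4e4),
                              n_genes = 40L, n_trnas = 0L,
                              n_trna_clusters = 0L, n_satellites = 0L,
                              ancestral_te_count = 0L)
  expect_error(simulate_ancestor(cfg_bad), "placement failure")
})

test_that("events are inherited along root-to-tip paths exactly", {
  sim <- small_sim()
  phy <- sim$phylogeny
  for (t in names(sim$genomes)) {
    carried <- sim$genomes[[t]]$events$event_id
    expected <- sim$truth$event_id[sim$truth$branch %in% taxon_path(phy, t)]
    expect_setequal(carried, expected)
  }
})

test_that("planted event counts follow the Poisson expectation", {
  # stem TE rate chosen for an expected 30 insertions per replicate
  mb <- 0.2; dur <- 2.25
  rate <- 30 / (mb * dur)
  counts <- vapply(1:20, function(s) {
    cfg <- evolution_config(seed = 7L + s,
                            chrom_lengths = c(chrA = 1e5, chrB = 1e5),
                            n_genes = 6L, n_trnas = 4L, n_trna_clusters = 1L,
                            n_satellites = 0L, ancestral_te_count = 0L,
                            te_rate = c(dsim = 0, dmau = 0, dsec = 0,
                                        stem = rate, dmel = 0, dyak = 0),
                            inversion_rate = 0, tandem_dup_rate = 0,
                            dispersed_dup_rate = 0, satellite_change_rate = 0,
                            trna_dup_rate = 0, trna_del_rate = 0,
                            trna_anticodon_rate = 0, intron_indel_rate = 0,
                            sub_rate = 0)
    sim <- suppressWarnings(simulate_complex(cfg))
    sum(sim$truth$type == "te_insertion" & sim$truth$branch == "stem")
  }, numeric(1))
  # mean of 20 replicates within 3 standard errors of the Poisson mean
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / 20))
  expect_gt(stats::var(counts), 0)
})

test_that("heterochromatin receives the configured excess of inversions", {
  sim <- small_sim()
  inv <- truth_coords(sim, "dmel")[type == "inversion"]
  inv <- merge(inv, sim$truth[, list(event_id, payload)], by = "event_id")
  comp <- sub("compartment=([a-z]+);.*", "\\1", inv$payload)
  expect_gte(mean(comp == "het"), 0.9)
})

test_that("carried event coordinates stay consistent with derived genomes", {
  sim <- small_sim()
  # a TE insertion's derived interval must exceed its zero-width ancestral
  # anchor by the payload length
  tes <- sim$truth[sim$truth$type == "te_insertion" & sim$truth$branch == "stem", ]
  tc <- truth_coords(sim, "dsim")
  tc <- tc[tc$event_id %in% tes$event_id, ]
  lens <- as.integer(sub(".*len=([0-9]+);.*", "\\1", tes$payload))
  exact <- (tc$end - tc$start) == lens[match(tc$event_id, tes$event_id)]
  # nested later events (an indel inside a TE-bearing intron, a TE into a
  # TE) legitimately resize a few carried intervals
  expect_gte(mean(exact), 0.8)
  expect_true(all(tc$end >= tc$start))
})
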