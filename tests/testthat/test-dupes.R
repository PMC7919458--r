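random_seq2 <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("an in-place copied segment is called as one tandem duplication", {
  s <- random_seq2(1e5, 31)
  ds <- 40000; de <- 42000
  q <- paste0(substr(s, 1, de), substr(s, ds + 1, de), substr(s, de + 1, nchar(s)))
  m <- build_map(c(c1 = s), c(c1 = q))
  calls <- detect_duplications(m)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$arrangement, "tandem")
  expect_equal(calls$copies, 2L)
  tol <- m$k + m$max_gap
  expect_lt(abs(calls$start - ds), tol)
  expect_lt(abs(calls$end - de), tol)
  # identical genomes: no calls
  expect_equal(nrow(detect_duplications(build_map(c(c1 = s), c(c1 = s)))), 0L)
})

test_that("a copy inserted on another chromosome is dispersed", {
  s1 <- random_seq2(6e4, 32); s2 <- random_seq2(6e4, 33)
  seg <- substr(s1, 20001, 22000)
  q2 <- paste0(substr(s2, 1, 30000), seg, substr(s2, 30001, nchar(s2)))
  m <- build_map(c(c1 = s1, c2 = s2), c(c1 = s1, c2 = q2))
  calls <- detect_duplications(m)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$arrangement, "dispersed")
  expect_equal(calls$chrom, "c1")
})

test_that("duplication polarization implements the stem arithmetic", {
  phy <- simcomplex_phylogeny()
  mk <- function(starts) data.table::data.table(
    chrom = "c1", start = starts, end = starts + 1000,
    copies = 2L, arrangement = "tandem",
    qry_chroms = "c1", qry_starts = "0", qry_ends = "0")
  # 97 candidate loci shared by the whole ingroup; 11 also in the outgroup
  starts <- seq(0, by = 5000, length.out = 97)
  calls <- list(dsim = mk(starts), dmau = mk(starts), dsec = mk(starts))
  og <- mk(starts[1:11])
  pol <- polarize_duplications(calls, og, phy)
  expect_equal(pol$n_ingroup_shared, 97L)
  expect_equal(pol$n_outgroup_overlap, 11L)
  expect_equal(pol$n_stem, 86L)
  expect_equal(pol$n_stem, pol$n_ingroup_shared - pol$n_outgroup_overlap)

  # single-taxon call: terminal branch; outgroup + full ingroup but not
  # reference: flagged, not a stem gain
  calls2 <- list(dsim = mk(c(0, 5000)), dmau = mk(0), dsec = mk(0))
  pol2 <- polarize_duplications(calls2, mk(0), phy)
  ev <- pol2$events[order(pol2$events$start), ]
  expect_equal(ev$status, c("outgroup_shared", "terminal"))
  expect_equal(ev$branch, c(NA, "dsim"))
  expect_equal(pol2$n_stem, 0L)
})

test_that("gene-overlap classes are maximal and nested", {
  genes <- data.table::data.table(gene_id = "g1", chrom = "c1", strand = "+",
                                  cds_start = 1100, cds_end = 1900)
  exons <- data.table::data.table(gene_id = "g1", chrom = "c1", strand = "+",
                                  exon_rank = 1:2,
                                  start = c(1000, 1600), end = c(1300, 2000))
  cls <- function(s, e) classify_overlap(
    data.table::data.table(chrom = "c1", start = s, end = e),
    genes, exons)$overlap_class
  expect_equal(cls(900, 2100), "full_gene")    # whole transcript + UTRs
  expect_equal(cls(1050, 1950), "full_CDS")    # truncates the UTRs only
  expect_equal(cls(1250, 1500), "exonic")
  expect_equal(cls(3000, 4000), "intergenic")
  # nesting: full_gene implies full_CDS implies exonic
  expect_true(all(c("full_gene", "full_CDS") %in%
                    c("full_gene", "full_CDS", "exonic")))
})

test_that("X enrichment reproduces the published proportion tests", {
  mk_calls <- function(nx, na) data.table::data.table(
    chrom = c(rep("chrX", nx), rep("chr2", na)), start = 0, end = 1)
  r <- x_enrichment(mk_calls(43, 43), null_prop = 0.158)
  expect_equal(r$x_count, 43L)
  expect_lt(r$test$p_value, 1e-10)
  r2 <- x_enrichment(mk_calls(15, 17), null_prop = 0.158)
  expect_equal(r2$test$p_value, 4.7e-6, tolerance = 0.05)
  # observation at the null: p ~ 1
  r3 <- x_enrichment(mk_calls(5, 27), null_prop = round(32 * 0.158) / 32,
                     continuity = FALSE)
  expect_gt(r3$test$p_value, 0.9)
  expect_error(x_enrichment(mk_calls(0, 0), 0.158), "no calls")
})

test_that("duplication rates mirror the published per-Myr figures", {
  r <- duplication_rate(32, 2.5)
  expect_equal(r$rate, 12.8)
  expect_equal(r$years_per_gene, 78125)
  expect_equal(duplication_rate(62, 2.5)$rate, 24.8)
  expect_true(is.na(duplication_rate(0, 2.5)$years_per_gene))
})

test_that("planted tandem duplications are recovered from the simulated maps", {
  sim <- small_sim()
  maps <- ref_maps()
  tol <- maps$dsim$k + maps$dsim$max_gap
  hits <- 0L; total <- 0L
  for (t in sim$phylogeny$ingroup) {
    calls <- detect_duplications(maps[[t]])
    tru <- truth_coords(sim, "dmel")
    tru <- merge(tru, sim$truth[, list(event_id, payload)], by = "event_id")
    tru <- tru[tru$type == "tandem_dup" &
                 tru$branch %in% c("stem", t) &
                 tru$end - tru$start >= 1000, ]
    for (i in seq_len(nrow(tru))) {
      total <- total + 1L
      ok <- any(calls$chrom == tru$chrom[i] &
                  abs(calls$start - tru$start[i]) < tol &
                  abs(calls$end - tru$end[i]) < tol)
      hits <- hits + ok
    }
  }
  skip_if(total < 5)
  expect_gte(hits / total, 0.8)
})
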