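# build a minimal genome-state stand-in with gene models only
mk_gene_state <- function(exon_lens, intron_lens, chrom = "c1", start = 1000,
                          gene_id = "g1", strand = "+") {
  n <- length(exon_lens)
  starts <- start + cumsum(c(0, utils::head(exon_lens, -1) + intron_lens))
  ends <- starts + exon_lens
  list(exons = data.table::data.table(
    gene_id = gene_id, chrom = chrom, strand = strand,
    exon_rank = if (strand == "+") seq_len(n) else rev(seq_len(n)),
    start = starts, end = ends),
    genes = data.table::data.table(gene_id = gene_id, chrom = chrom,
                                   strand = strand, cds_start = start + 10,
                                   cds_end = max(ends) - 10))
}

test_that("the 10 percent flanking-exon rule is applied symmetrically", {
  gA <- mk_gene_state(c(100, 200, 300), c(500, 500))
  gB <- mk_gene_state(c(100, 210, 300), c(650, 480))
  ci <- match_conserved_introns(list(ref = gA, alt = gB), ref_taxon = "ref")
  # intron 1 flanked by 100/100 and 200/210 (5%): retained;
  # intron 2 flanked by 200/210 and 300/300: retained
  expect_equal(sort(unique(ci$intron_rank)), c(1L, 2L))
  expect_equal(ci$length[ci$taxon == "alt" & ci$intron_rank == 1], 650)

  # a 200 vs 250 flank (25% of the smaller, 20% of the larger) is excluded
  gC <- mk_gene_state(c(100, 250, 300), c(500, 500))
  ci2 <- match_conserved_introns(list(ref = gA, alt = gC), ref_taxon = "ref")
  expect_false(1L %in% ci2$intron_rank)
  expect_false(2L %in% ci2$intron_rank)   # second flank also shifted
})

test_that("unequal exon counts exclude whole genes", {
  gA <- mk_gene_state(c(100, 200, 300), c(500, 500))
  gB <- mk_gene_state(c(100, 200), 500)
  ci <- match_conserved_introns(list(ref = gA, alt = gB), ref_taxon = "ref")
  expect_equal(nrow(ci), 0L)
})

test_that("complex/simple classification needs only one bp of repeat overlap", {
  introns <- data.table::data.table(
    gene_id = "g1", intron_rank = 1:2, taxon = "t", chrom = "c1",
    start = c(1000, 5000), end = c(2000, 6000),
    length = c(1000, 1000))
  reps <- data.table::data.table(chrom = "c1", start = 1999, end = 2100)
  out <- classify_intron(introns, reps)
  expect_equal(out$class, c("complex", "simple"))
  # complex + simple partition the set
  expect_equal(sum(out$class == "complex") + sum(out$class == "simple"),
               nrow(out))
})

test_that("paired length comparison handles identical and degenerate input", {
  ci <- data.table::data.table(
    gene_id = rep(paste0("g", 1:10), 2), intron_rank = 1L,
    taxon = rep(c("a", "b"), each = 10), chrom = "c1",
    start = 0, end = 1000, length = rep(c(500, 500), each = 10),
    class = "simple")
  cmp <- compare_intron_lengths(ci, "a", "b")
  expect_equal(cmp$mean_diff, 0)
  expect_true(cmp$test$degenerate)
  expect_equal(cmp$test$p_value, 1)

  # constant +2 bp shift: zero variance of differences is flagged, not
  # reported as an absurdly significant t statistic
  ci2 <- data.table::copy(ci)
  ci2$length[ci2$taxon == "a"] <- 502
  cmp2 <- compare_intron_lengths(ci2, "a", "b")
  expect_equal(cmp2$mean_diff, 2)
  expect_true(cmp2$test$degenerate)
})

test_that("type-I error stays near nominal under the null", {
  # substitution-only evolution leaves intron lengths untouched; simulate
  # paired-difference noise at the pipeline's analysis step instead
  set.seed(23)
  rejections <- mean(replicate(200, {
    d <- rnorm(60)
    paired_t(d)$p_value < 0.05
  }))
  expect_lt(rejections, 0.05 + 0.04)
})

test_that("a planted directional intron effect is detected and estimated", {
  sim <- intron_scenario()
  g <- sim$genomes
  four <- c("dmel", "dsim", "dmau", "dsec")
  ci <- match_conserved_introns(g[four], taxa = four, ref_taxon = "dmel")
  ci <- data.table::rbindlist(lapply(four, function(t)
    classify_intron(ci[ci$taxon == t, ], g[[t]]$repeats)))
  cmp <- compare_intron_lengths(ci, "dmel", "dsim")
  expect_lt(cmp$test$p_value, 0.01)
  expect_gt(cmp$mean_diff, 0)
  expected <- ledger_intron_diff(sim, ci, "dmel", "dsim")
  expect_equal(cmp$mean_diff, expected, tolerance = 0.10)
})
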