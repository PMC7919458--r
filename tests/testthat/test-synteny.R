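random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("anchors tile identical sequences and respect strand symmetry", {
  s <- random_seq(10000, 1)
  a <- find_anchors(c(c1 = s), c(c1 = s), k = 15)
  expect_true(all(a$strand == 1L))
  cov <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(a$ref_start + 1, a$ref_end))))
  expect_gte(cov, 10000 - 2 * (15 - 1))

  rc <- syntevo:::revcomp_chr(s)
  b <- find_anchors(c(c1 = s), c(c1 = rc), k = 15)
  expect_true(all(b$strand == -1L))
  expect_error(find_anchors(c(c1 = s), c(c1 = s), k = 14), "odd")
  expect_error(find_anchors(c(c1 = s), c(c1 = s), k = 9), "odd integer >= 11")
})

test_that("a single SNP splits the anchor tiling exactly as the k-mer table predicts", {
  s <- random_seq(1000, 2)
  q <- s
  substr(q, 500, 500) <- setdiff(c("A", "C", "G", "T"), substr(s, 500, 500))[1]
  a <- find_anchors(c(c1 = s), c(c1 = q), k = 15)
  # no anchor spans the changed base
  expect_false(any(a$ref_start < 499 & a$ref_end > 500))
  # brute-force oracle: shared unique 15-mers flank position 499 in two runs
  kmers <- function(x) substring(x, 1:(nchar(x) - 14), 15:nchar(x))
  tr <- table(kmers(s)); tq <- table(kmers(q))
  shared <- intersect(names(tr)[tr == 1], names(tq)[tq == 1])
  pos <- sort(match(shared, kmers(s)))
  runs <- cumsum(c(1, diff(pos) != 1))
  expect_equal(length(unique(runs)), 2L)
  expect_equal(nrow(a), 2L)
})

test_that("chaining produces one block for identical chromosomes and obeys max_gap", {
  s <- random_seq(20000, 3)
  m <- build_map(c(c1 = s), c(c1 = s), k = 15, min_block = 1000)
  expect_equal(nrow(m$blocks), 1L)
  expect_equal(m$blocks$strand, 1L)

  # one SNP in the middle with max_gap = 0: two blocks
  q <- s
  substr(q, 10000, 10000) <- setdiff(c("A", "C", "G", "T"),
                                     substr(s, 10000, 10000))[1]
  m2 <- build_map(c(c1 = s), c(c1 = q), k = 15, max_gap = 0, min_block = 1000)
  expect_equal(nrow(m2$blocks), 2L)
})

test_that("a planted inversion yields the +/-/+ block structure at the right place", {
  s <- random_seq(60000, 4)
  inv_s <- 20000; inv_e <- 40000
  q <- paste0(substr(s, 1, inv_s),
              syntevo:::revcomp_chr(substr(s, inv_s + 1, inv_e)),
              substr(s, inv_e + 1, nchar(s)))
  m <- build_map(c(c1 = s), c(c1 = q))
  b <- m$blocks[order(m$blocks$ref_start), ]
  expect_equal(b$strand, c(1L, -1L, 1L))
  expect_lt(abs(b$ref_start[2] - inv_s), m$k + 50)
  expect_lt(abs(b$ref_end[2] - inv_e), m$k + 50)
})

test_that("block extents are pairwise disjoint in both genomes", {
  for (m in ref_maps()) {
    for (side in c("ref", "qry")) {
      b <- m$blocks
      cs <- paste0(side, "_chrom")
      for (ch in unique(b[[cs]])) {
        bb <- b[b[[cs]] == ch, ]
        ir <- IRanges::IRanges(bb[[paste0(side, "_start")]] + 1,
                               bb[[paste0(side, "_end")]])
        expect_equal(sum(IRanges::width(IRanges::reduce(ir))),
                     sum(IRanges::width(ir)))
      }
    }
  }
})

test_that("alignment summary recovers planted divergence", {
  # two descendants of one ancestor, each mutated at 2.5% of sites:
  # expected observed divergence ~5%, identity 0.95 +/- 0.01
  anc <- random_seq(2e5, 6)
  mutate <- function(x, p, seed) {
    set.seed(seed)
    n <- nchar(x)
    pos <- sample.int(n, round(p * n))
    r <- charToRaw(x)
    cur <- rawToChar(r[pos], multiple = TRUE)
    new <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1))
    r[pos] <- charToRaw(paste(new, collapse = ""))
    rawToChar(r)
  }
  g1 <- mutate(anc, 0.025, 61)
  g2 <- mutate(anc, 0.025, 62)
  m <- build_map(c(c1 = g1), c(c1 = g2))
  s <- summarize_alignment(m)
  expect_equal(s$mean_block_identity, 0.95, tolerance = 0.011)
  expect_gt(s$ref_aligned_fraction, 0.98)
})

test_that("species-specific insertions register as unaligned sequence", {
  s <- random_seq(3e5, 7)
  set.seed(8)
  ins_at <- sort(sample(seq(2e4, 2.8e5, by = 1e4), 10))
  q <- s
  for (p in rev(ins_at))
    q <- paste0(substr(q, 1, p), random_seq(6000, p), substr(q, p + 1, nchar(q)))
  m <- build_map(c(c1 = s), c(c1 = q))
  s2 <- summarize_alignment(m, identity = FALSE)
  planted_frac <- 60000 / nchar(q)
  expect_gte(1 - s2$qry_aligned_fraction, planted_frac - 0.03)
})

test_that("interval projection is exact, orientation-aware and invertible", {
  s <- random_seq(50000, 9)
  m <- build_map(c(c1 = s), c(c1 = s), k = 15)
  img <- project_interval(m, "c1", 1000, 2000)
  expect_equal(nrow(img), 1L)
  expect_equal(img$start, 1000)
  expect_equal(img$end, 2000)
  expect_false(img$split)

  # reverse-complement query: image offsets measured from the block end
  rc <- syntevo:::revcomp_chr(s)
  m2 <- build_map(c(c1 = s), c(c1 = rc), k = 15)
  img2 <- project_interval(m2, "c1", 1000, 2000)
  expect_equal(img2$strand, -1L)
  expect_lt(abs(img2$start - (nchar(s) - 2000)), 30)
  # round trip back to the reference
  back <- project_interval(m2, img2$chrom, img2$start, img2$end, from = "qry")
  expect_lt(abs(back$start - 1000), 30)
  expect_lt(abs(back$end - 2000), 30)
  expect_error(project_interval(m, "c1", -5, 100), "outside")
})

test_that("an interval spanning a block boundary projects as split images", {
  sim <- small_sim()
  m <- ref_maps()$dsim
  b <- m$blocks[order(m$blocks$ref_start), ]
  b <- b[b$ref_chrom == b$ref_chrom[1], ]
  skip_if(nrow(b) < 2L)
  # straddle the junction between the first two blocks of a chromosome
  s1 <- b$ref_end[1] - 500
  e1 <- b$ref_start[2] + 500
  img <- project_interval(m, b$ref_chrom[1], s1, e1)
  expect_gte(nrow(img), 1L)
  expect_true(all(img$split))
})

test_that("substitution-only genomes give one block per chromosome", {
  cfg <- evolution_config(seed = 21L, chrom_lengths = c(chrA = 2e5),
                          n_genes = 10L, n_trnas = 4L, n_trna_clusters = 1L,
                          n_satellites = 0L, ancestral_te_count = 0L,
                          te_rate = 0, inversion_rate = 0, tandem_dup_rate = 0,
                          dispersed_dup_rate = 0, satellite_change_rate = 0,
                          trna_dup_rate = 0, trna_del_rate = 0,
                          trna_anticodon_rate = 0, intron_indel_rate = 0)
  sim <- suppressWarnings(simulate_complex(cfg))
  m <- build_map(sim$genomes$dmel, sim$genomes$dsim)
  expect_equal(nrow(m$blocks), 1L)
})
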