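mk_trnas <- function(iso, chrom = "c1", start0 = 1000, gap = 300,
                     taxon_tag = "t", pseudo = NULL, anticodons = NULL) {
  n <- length(iso)
  if (is.null(pseudo)) pseudo <- rep(FALSE, n)
  if (is.null(anticodons))
    anticodons <- vapply(iso, function(a) syntevo:::aa_anticodons(a)[1],
                         character(1))
  data.table::data.table(
    trna_id = paste0(taxon_tag, seq_len(n)), chrom = chrom,
    start = start0 + (seq_len(n) - 1L) * (72L + gap),
    end = start0 + (seq_len(n) - 1L) * (72L + gap) + 72L,
    strand = "+", isotype = iso, anticodon = anticodons,
    pseudogene = pseudo, cluster_id = "cl1")
}

test_that("isotype strings encode order, pseudogenes and clusters", {
  tr <- mk_trnas(c("A", "A", "R"), pseudo = c(FALSE, TRUE, FALSE))
  s <- build_isotype_string(tr, "c1")
  expect_equal(s$string, "AaR")
  expect_equal(s$clusters, c(1L, 1L, 1L))
  # far-apart genes break clusters
  tr2 <- mk_trnas(c("A", "R"), gap = 300)
  tr2$start[2] <- tr2$start[2] + 10000
  tr2$end[2] <- tr2$start[2] + 72
  expect_equal(build_isotype_string(tr2, "c1")$clusters, c(1L, 2L))
  expect_equal(build_isotype_string(tr, "chr_none")$string, "")
  tr3 <- mk_trnas("A"); tr3$isotype <- "?"
  tr3$anticodon <- "AAA"
  expect_warning(build_isotype_string(tr3, "c1"), "unknown isotype")
})

test_that("alignment scores equal the exhaustive enumeration oracle", {
  set.seed(17)
  alpha <- c("A", "R", "G", "S")
  for (r in 1:40) {
    sA <- paste(sample(alpha, sample(0:8, 1), replace = TRUE), collapse = "")
    sB <- paste(sample(alpha, sample(1:8, 1), replace = TRUE), collapse = "")
    expect_equal(align_isotype_strings(sA, sB)$score,
                 syntevo:::align_score_bruteforce(sA, sB),
                 info = paste(sA, sB))
  }
  al <- align_isotype_strings("AAR", "AAR")
  expect_equal(nrow(al$columns), 3L)
  expect_false(any(is.na(al$columns)))
})

test_that("alignment tie-breaking is deterministic", {
  a1 <- align_isotype_strings("AAR", "AR")$columns
  a2 <- align_isotype_strings("AAR", "AR")$columns
  expect_identical(a1, a2)
  # exactly one gap column, and it falls on the first A by the tie rule
  expect_equal(sum(is.na(a1$b_pos)), 1L)
  expect_equal(a1$a_pos[is.na(a1$b_pos)], 1L)
})

test_that("positional orthology conserves genes and detects shifts by kind", {
  phy <- simcomplex_phylogeny()
  base_iso <- c("P", "S", "R", "G", "N")
  tabs <- lapply(stats::setNames(phy$taxa, phy$taxa), function(t)
    mk_trnas(base_iso, taxon_tag = t))
  # dsim gets an isoacceptor change at position 2 (Ser AGA -> Ser TGA)
  tabs$dsim$anticodon[2] <- "TGA"
  # dsec gets an alloacceptor change at position 4: Gly ACC -> Ala AGC,
  # a single-base anticodon mutation that changes the decoded amino acid
  tabs$dsec$isotype[4] <- "A"
  tabs$dsec$anticodon[4] <- "AGC"
  res <- trna_orthology(tabs, phy)
  expect_equal(nrow(res$columns), 5L)
  n_genes_in <- sum(vapply(tabs, nrow, numeric(1)))
  n_assigned <- sum(!is.na(as.matrix(
    res$columns[, paste0(phy$taxa, "_id"), with = FALSE])))
  expect_equal(n_assigned, n_genes_in)

  sh <- res$shifts
  expect_equal(nrow(sh), 2L)
  iso_row <- sh[sh$kind == "isoacceptor", ]
  expect_equal(iso_row$anc_anticodon, "AGA")
  expect_equal(iso_row$der_anticodon, "TGA")
  expect_equal(iso_row$branch, "dsim")
  allo_row <- sh[sh$kind == "alloacceptor", ]
  expect_equal(allo_row$der_isotype, "A")
  expect_equal(allo_row$branch, "dsec")
})

test_that("copy gains and losses are polarized against the outgroup", {
  phy <- simcomplex_phylogeny()
  base_iso <- c("P", "S", "R", "G")
  tabs <- lapply(stats::setNames(phy$taxa, phy$taxa), function(t)
    mk_trnas(base_iso, taxon_tag = t))
  # dmau lost gene 3; outgroup still has it -> loss on the dmau terminal
  tabs$dmau <- tabs$dmau[-3, ]
  res <- trna_orthology(tabs, phy)
  loss <- res$columns[res$columns$call == "copy_loss", ]
  expect_equal(nrow(loss), 1L)
  expect_equal(loss$branch, "dmau")
})

test_that("column membership is invariant to taxon input order", {
  phy <- simcomplex_phylogeny()
  tabs <- lapply(stats::setNames(phy$taxa, phy$taxa), function(t)
    mk_trnas(c("P", "S", "R"), taxon_tag = t))
  tabs$dsec <- tabs$dsec[-2, ]
  r1 <- trna_orthology(tabs, phy)
  r2 <- trna_orthology(rev(tabs), phy)
  cols <- function(r) r$columns[order(r$columns$anchor),
                                paste0(phy$taxa, "_id"), with = FALSE]
  expect_equal(as.data.frame(cols(r1)), as.data.frame(cols(r2)))
})

test_that("planted cluster mutations are recovered from the simulation", {
  sim <- small_sim()
  res <- trna_orthology(lapply(sim$genomes, function(x) x$trnas),
                        sim$phylogeny)
  # conservation: every input gene lands in exactly one column
  n_in <- sum(vapply(sim$genomes, function(g) nrow(g$trnas), numeric(1)))
  n_cols <- sum(!is.na(as.matrix(
    res$columns[, paste0(sim$phylogeny$taxa, "_id"), with = FALSE])))
  expect_equal(n_cols, n_in)

  # every planted duplication shows up as a copy gain on its branch
  tru <- sim$truth[sim$truth$type == "trna_change", ]
  dups <- tru[grepl("kind=dup", tru$payload), ]
  gains <- res$columns[res$columns$call == "copy_gain", ]
  for (b in unique(dups$branch))
    expect_gte(sum(gains$branch == b, na.rm = TRUE),
               sum(dups$branch == b))
})

test_that("anticodon arithmetic is consistent with the genetic code", {
  expect_equal(anticodon_to_aa("CAT"), "M")   # codon ATG
  expect_equal(anticodon_to_aa("CGT"), "T")   # codon ACG: the Met>Thr shift
  nb <- syntevo:::anticodon_neighbors("CAT")
  expect_true("CGT" %in% nb$allo)
  expect_true(all(anticodon_to_aa(nb$iso) == "M"))
})
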