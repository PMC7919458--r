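test_that("containment keeps fully embedded repeats only", {
  s <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE), collapse = "")
  m <- build_map(c(c1 = s), c(c1 = s), k = 15)
  b <- m$blocks
  reps <- data.table::data.table(
    repeat_id = c("in", "edge"), chrom = "c1",
    start = c(b$ref_start[1] + 100, b$ref_end[1] - 50),
    end = c(b$ref_start[1] + 200, b$ref_end[1] + 50),
    strand = "+", family = "f", class = "DNA")
  kept <- contained_repeats(reps, m, side = "ref")
  expect_equal(kept$repeat_id, "in")
})

test_that("identical genomes share every repeat; private repeats stay unshared", {
  s <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE), collapse = "")
  m <- build_map(c(c1 = s), c(c1 = s), k = 15)
  reps <- data.table::data.table(
    repeat_id = paste0("r", 1:3), chrom = "c1",
    start = c(1000, 9000, 20000), end = c(1900, 9800, 21000),
    strand = "+", family = "f", class = c("DNA", "LTR", "DNA"))
  sh <- shared_repeat_content(reps, reps, m)
  expect_setequal(sh$id_a, reps$repeat_id)
  expect_equal(sum(sh$shared_bp[match(reps$repeat_id, sh$id_a)]),
               sum(reps$end - reps$start))
  # a repeat absent from B is unshared
  sh2 <- shared_repeat_content(reps, reps[1:2, ], m)
  expect_false("r3" %in% sh2$id_a)
  # class must match even at the same position
  repsB <- data.table::copy(reps)
  repsB$class <- "nonLTR"
  expect_equal(nrow(shared_repeat_content(reps, repsB, m)), 0L)
})

test_that("branch assignment implements the pairwise set algebra", {
  focal <- data.table::data.table(
    repeat_id = paste0("r", 1:5), chrom = "c1",
    start = (1:5) * 1000, end = (1:5) * 1000 + 500,
    strand = "+", family = "f", class = "DNA")
  pair <- function(ids) data.table::data.table(
    id_a = ids, id_b = ids, class = "DNA", shared_bp = 500)
  shared <- list(dsec = pair(c("r1", "r2")), dsim = pair(c("r1", "r2", "r3")),
                 dmel = pair(c("r1", "r4")))
  asn <- assign_branches(focal, shared, focal = "dmau", reference = "dmel")
  expect_equal(asn$category,
               c("complex_wide",    # shared with both ingroup + reference
                 "ingroup_stem",    # both ingroup, not reference
                 "pair_dsim", "pair_dmel",
                 "specific_dmau"))
})

test_that("composition proportions sum to one within categories", {
  asn <- data.table::data.table(
    repeat_id = paste0("r", 1:3), class = c("DNA", "LTR", "nonLTR"),
    bp = c(30, 60, 10), partners = "", category = "ingroup_stem")
  comp <- composition_summary(asn)
  expect_equal(comp$prop[order(comp$class)], c(0.3, 0.6, 0.1))
  expect_equal(sum(comp$prop), 1)
})

test_that("exonic accounting splits repeat bases at exon boundaries", {
  asn <- data.table::data.table(repeat_id = c("a", "b"), class = "DNA",
                                bp = c(100, 100), partners = "",
                                category = c("x", "y"))
  reps <- data.table::data.table(repeat_id = c("a", "b"), chrom = "c1",
                                 start = c(100, 500), end = c(200, 600))
  exons <- data.table::data.table(chrom = "c1", start = 100, end = 200)
  out <- exonic_overlap(asn, reps, exons)
  expect_equal(out$exonic_frac[out$category == "x"], 1)
  expect_equal(out$exonic_frac[out$category == "y"], 0)
})

test_that("category bp totals partition the containment-filtered repeat bp", {
  sim <- small_sim()
  sta <- shared_te_analysis(sim$genomes, focal_maps(), focal = "dmau",
                            reference = "dmel")
  expect_equal(sum(sta$assignment$bp),
               sum(sta$contained$end - sta$contained$start))
  expect_equal(nrow(sta$assignment), nrow(sta$contained))
  # proportions are within-category normalized
  sums <- sta$composition[, list(s = sum(prop)), by = "category"]
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("planted stem TEs are assigned to the ingroup stem", {
  sim <- small_sim()
  sta <- shared_te_analysis(sim$genomes, focal_maps(), focal = "dmau",
                            reference = "dmel")
  asn <- sta$assignment
  # planted stem insertions carry ledger ids; those that survived the
  # containment filter should be called ingroup_stem
  stem_ids <- grep("^stem_te", asn$repeat_id, value = TRUE)
  skip_if(length(stem_ids) < 5)
  cat_of <- asn$category[match(stem_ids, asn$repeat_id)]
  expect_gte(mean(cat_of == "ingroup_stem"), 0.8)
  # ancestral TEs that survived containment should mostly be complex-wide
  anc_ids <- grep("^anc_te", asn$repeat_id, value = TRUE)
  skip_if(length(anc_ids) < 5)
  expect_gte(mean(asn$category[match(anc_ids, asn$repeat_id)] == "complex_wide"),
             0.7)
})
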