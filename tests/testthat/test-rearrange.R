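test_that("block permutations capture collinearity and single inversions", {
  s <- paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE), collapse = "")
  m <- build_map(c(c1 = s), c(c1 = s), k = 15)
  p <- blocks_to_permutation(m)
  expect_equal(unname(p$c1), 1L)
  expect_equal(count_breakpoints(p), 0L)

  q <- paste0(substr(s, 1, 20000),
              syntevo:::revcomp_chr(substr(s, 20001, 40000)),
              substr(s, 40001, nchar(s)))
  m2 <- build_map(c(c1 = s), c(c1 = q))
  p2 <- blocks_to_permutation(m2)
  expect_equal(unname(p2$c1), c(1L, -2L, 3L))
  expect_equal(count_breakpoints(p2), 2L)
  calls <- call_inversions(p2, m2)
  expect_equal(nrow(calls), 1L)
})

test_that("breakpoint counts match a direct adjacency scan on random permutations", {
  set.seed(11)
  for (r in 1:50) {
    v <- sample.int(8) * sample(c(-1L, 1L), 8, replace = TRUE)
    expect_equal(count_breakpoints(v), breakpoints_oracle(v))
  }
  expect_equal(count_breakpoints(c(1L, -2L, 3L)), 2L)
  expect_equal(count_breakpoints(1:5), 0L)
})

test_that("inversion caller reports maximal reversed runs", {
  perm <- structure(list(c1 = stats::setNames(c(1L, -3L, -2L, 4L),
                                              c(1L, 3L, 2L, 4L))),
                    class = "signed_permutation", topology = "linear")
  fake_map <- list(blocks = data.table::data.table(
    block_id = 1:4, ref_chrom = "c1",
    ref_start = c(0, 100, 200, 300), ref_end = c(100, 200, 300, 400)))
  calls <- call_inversions(perm, fake_map)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 100)
  expect_equal(calls$end, 300)
  expect_equal(calls$n_blocks, 2L)
  id <- structure(list(c1 = stats::setNames(1:4, 1:4)),
                  class = "signed_permutation", topology = "linear")
  expect_equal(nrow(call_inversions(id, fake_map)), 0L)
})

test_that("DCJ distance satisfies the closed-form expectations", {
  expect_equal(dcj_distance(list(1:4), list(1:4), "circular"), 0L)
  expect_equal(dcj_distance(list(1:4), list(1:4), "linear"), 0L)
  expect_equal(dcj_distance(list(c(1L, 2L, 3L, 4L)),
                            list(c(1L, -3L, -2L, 4L)), "circular"), 1L)
  expect_error(dcj_distance(list(1:3), list(1:4)), "marker set")
})

test_that("DCJ distance equals the brute-force BFS oracle", {
  set.seed(12)
  for (topo in c("circular", "linear")) {
    for (n in 3:5) {
      tab <- dcj_bfs_table(as.list(seq_len(n))[1], topo)
      tab <- dcj_bfs_table(list(seq_len(n)), topo)
      for (r in 1:60) {
        g <- random_signed_genome(n)
        expect_equal(dcj_distance(list(seq_len(n)), g, topo), tab(g),
                     info = paste(topo, n, paste(g[[1]], collapse = ",")))
      }
    }
  }
})

test_that("DCJ is a metric and bounded by the breakpoint count", {
  set.seed(13)
  for (r in 1:30) {
    n <- sample(3:6, 1)
    A <- random_signed_genome(n); B <- random_signed_genome(n)
    C <- random_signed_genome(n)
    dAB <- dcj_distance(A, B, "linear")
    expect_equal(dcj_distance(A, A, "linear"), 0L)
    expect_equal(dAB, dcj_distance(B, A, "linear"))
    expect_lte(dAB, dcj_distance(A, C, "linear") + dcj_distance(C, B, "linear"))
    # DCJ <= breakpoints of B relative to the identity when A is identity
    v <- random_signed_genome(n)[[1]]
    expect_lte(dcj_distance(list(seq_len(n)), list(v), "linear"),
               count_breakpoints(v))
  }
})

test_that("compartment classification uses midpoints and treats straddlers as het", {
  comp <- data.table::data.table(chrom = "c1", start = c(0, 500),
                                 end = c(500, 1000), name = c("eu", "het"))
  calls <- data.table::data.table(chrom = "c1",
                                  start = c(100, 450, 700),
                                  end = c(200, 550, 800))
  out <- classify_compartment(calls, comp)
  expect_equal(out$compartment, c("eu", "het", "het"))
  expect_error(classify_compartment(
    data.table::data.table(chrom = "c1", start = 1500, end = 1600), comp),
    "outside")
})

test_that("multi-taxon inversion analysis polarizes planted inversions correctly", {
  sim <- small_sim()
  maps <- ref_maps()
  ia <- inversion_analysis(maps, sim$phylogeny,
                           compartments = sim$genomes$dmel$compartments)
  expect_gt(nrow(ia$events), 0L)
  # most calls are heterochromatic under the default het:eu multiplier
  expect_gte(mean(ia$events$compartment == "het"), 0.9)

  # recall and branch agreement against the truth ledger, scored on
  # planted inversions that do not overlap another planted event
  # matching tolerance follows the chaining slack; the isolation margin is
  # tighter at this compact scale or no planted event would qualify
  tol <- maps$dsim$k + maps$dsim$max_gap
  iso <- 3000
  tru <- truth_coords(sim, "dmel")
  tru <- tru[tru$type == "inversion", ]
  isolated <- vapply(seq_len(nrow(tru)), function(i) {
    o <- tru[-i, ]
    !any(o$chrom == tru$chrom[i] & o$start < tru$end[i] + iso &
           o$end > tru$start[i] - iso)
  }, logical(1))
  tru <- tru[isolated & tru$branch != "dyak", ]
  hit <- logical(nrow(tru))
  branch_ok <- logical(nrow(tru))
  for (i in seq_len(nrow(tru))) {
    ev <- ia$events[ia$events$chrom == tru$chrom[i] &
                      abs(ia$events$start - tru$start[i]) < tol &
                      abs(ia$events$end - tru$end[i]) < tol, ]
    hit[i] <- nrow(ev) > 0L
    branch_ok[i] <- nrow(ev) > 0L && tru$branch[i] %in% ev$branch
  }
  expect_gte(mean(hit), 0.9)
  expect_equal(branch_ok[hit], rep(TRUE, sum(hit)))
})
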