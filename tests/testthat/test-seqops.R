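# direct checks of the edit engine: coordinate updates and liftover

toy_state <- function() {
  st <- syntevo:::new_genome_state(list(c1 = strrep("ACGT", 250)))  # 1 kb
  st$repeats <- data.table::data.table(
    repeat_id = c("r1", "r2"), chrom = "c1", start = c(100, 600),
    end = c(200, 700), strand = "+", family = "f", class = "DNA")
  st$compartments <- data.table::data.table(chrom = "c1", start = c(0, 500),
                                            end = c(500, 1000),
                                            name = c("eu", "het"))
  st
}

test_that("insertion shifts, grows and preserves features correctly", {
  st <- syntevo:::seq_insert(toy_state(), "c1", 150, strrep("A", 50))
  expect_equal(nchar(st$seq$c1), 1050)
  # r1 spans the insertion point: grows
  expect_equal(unlist(st$repeats[1, c("start", "end")]), c(start = 100, end = 250))
  # r2 downstream: shifts
  expect_equal(unlist(st$repeats[2, c("start", "end")]), c(start = 650, end = 750))
  expect_equal(st$compartments$end, c(550, 1050))
})

test_that("deletion removes contained features and shifts the rest", {
  st <- syntevo:::seq_delete(toy_state(), "c1", 90, 210)   # removes r1 entirely
  expect_equal(nchar(st$seq$c1), 880)
  expect_equal(st$repeats$repeat_id, "r2")
  expect_equal(st$repeats$start, 480)
})

test_that("inversion reflects contained features and flips strand", {
  st <- syntevo:::seq_invert(toy_state(), "c1", 50, 250)
  r1 <- st$repeats[1, ]
  expect_equal(r1$start, 50 + 250 - 200)
  expect_equal(r1$end, 50 + 250 - 100)
  expect_equal(r1$strand, "-")
  # sequence is the reverse complement over the window
  orig <- toy_state()$seq$c1
  expect_equal(substr(st$seq$c1, 51, 250),
               syntevo:::revcomp_chr(substr(orig, 51, 250)))
})

test_that("forward lift then reverse lift restores intervals", {
  ops <- data.table::data.table(
    op = c("ins", "del", "inv"), chrom = "c1",
    s = c(100, 300, 500), e = c(150, 350, 700))
  # intervals chosen to stay clear of the edited regions in every frame
  for (iv in list(c(10, 50), c(160, 240), c(420, 470), c(720, 800))) {
    lifted <- syntevo:::lift_interval(ops, "c1", iv[1], iv[2])
    back <- syntevo:::unlift_interval(ops, "c1", lifted[[1]], lifted[[2]])
    expect_equal(unname(back), iv)
  }
  # a point inside inserted material reverse-lifts to the insertion site
  back <- syntevo:::unlift_interval(ops[1], "c1", 120, 130)
  expect_equal(unname(back), c(100, 100))
})

test_that("liftover is monotone within unrearranged segments", {
  sim <- small_sim()
  ops <- sim$genomes$dsec$ops
  pts <- seq(1000, 5e5, by = 7919)
  lifted <- vapply(pts, function(p)
    syntevo:::lift_interval(ops[ops$op != "inv", ], "chrX", p, p)[[1]],
    numeric(1))
  expect_true(all(diff(lifted) > 0))
})
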