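test_that("one-sample proportion test reproduces the published enrichment p-values", {
  # X-linked full-CDS duplicates: 15 of 32 against an X-linked gene
  # proportion of 0.158
  r1 <- prop_test_one_sample(15, 32, 0.158, "two_sided", continuity = TRUE)
  expect_equal(r1$p_value, 4.7e-6, tolerance = 0.05)
  # exonic duplicates fixed on the stem vs the polymorphic proportion
  r2 <- prop_test_one_sample(62, 86, 0.408, "greater", continuity = TRUE)
  expect_equal(r2$p_value, 3.41e-9, tolerance = 0.05)
  # X-linked tandem duplications: overwhelming enrichment
  r3 <- prop_test_one_sample(43, 86, 0.158, "two_sided", continuity = TRUE)
  expect_lt(r3$p_value, 1e-10)
})

test_that("z-test agrees with the base-R implementation across a grid", {
  for (x in c(0L, 3L, 16L, 29L, 32L)) {
    for (p0 in c(0.1, 0.5, 0.9)) {
      ours <- prop_test_one_sample(x, 32, p0, "two_sided", continuity = TRUE)
      ref <- suppressWarnings(stats::prop.test(x, 32, p = p0, correct = TRUE))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10,
                   info = paste(x, p0))
      # z^2 equals the chi-squared statistic
      expect_equal(ours$z^2, unname(ref$statistic), tolerance = 1e-8)
    }
  }
  # observation exactly at the null: z = 0, p = 1
  r <- prop_test_one_sample(16, 32, 0.5, "two_sided", continuity = FALSE)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
})

test_that("exact binomial p-values equal direct pmf enumeration", {
  enum_p <- function(x, n, p0, alternative) {
    pmf <- vapply(0:n, function(k) choose(n, k) * p0^k * (1 - p0)^(n - k),
                  numeric(1))
    switch(alternative,
           greater = sum(pmf[(x + 1):(n + 1)]),
           less = sum(pmf[1:(x + 1)]),
           two_sided = sum(pmf[pmf <= pmf[x + 1] * (1 + 1e-7)]))
  }
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(1:20, 1)
    x <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    for (alt in c("two_sided", "greater", "less")) {
      expect_equal(binom_exact(x, n, p0, alt), min(enum_p(x, n, p0, alt), 1),
                   tolerance = 1e-12, info = paste(x, n, round(p0, 3), alt))
    }
    # base-R cross-check
    expect_equal(binom_exact(x, n, p0, "two_sided"),
                 stats::binom.test(x, n, p0)$p.value, tolerance = 1e-9)
  }
  expect_equal(binom_exact(10, 10, 0.5, "greater"), 0.5^10)
  expect_equal(binom_exact(0, 10, 0.2, "less"), 0.8^10)
})

test_that("normal approximation converges to the exact binomial", {
  # grid within the approximation's working range: expected count >= 10,
  # observations up to ~2 standard deviations from the null
  for (n in c(100L, 400L, 1000L)) {
    for (p0 in c(0.2, 0.5)) {
      for (zdev in c(0.5, 1, 1.5)) {
        x <- round(n * p0 + zdev * sqrt(n * p0 * (1 - p0)))
        appr <- prop_test_one_sample(x, n, p0, "greater", continuity = TRUE)$p_value
        exact <- binom_exact(x, n, p0, "greater")
        expect_lt(abs(appr - exact) / exact, 0.10)
      }
    }
  }
})

test_that("two-sample proportion test is symmetric and matches prop.test", {
  r <- prop_test_two_sample(30, 100, 30, 100, continuity = FALSE)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  a <- prop_test_two_sample(40, 100, 20, 80)
  b <- prop_test_two_sample(20, 80, 40, 100)
  expect_equal(a$z, -b$z)
  expect_equal(a$p_value, b$p_value)
  ref <- stats::prop.test(c(40, 20), c(100, 80), correct = TRUE)
  expect_equal(a$p_value, ref$p.value, tolerance = 1e-10)
  # strongly unequal proportions, cross-checked against the exact
  # conditional (hypergeometric) oracle
  r2 <- prop_test_two_sample(9, 10, 1, 10)
  expect_lt(r2$p_value, 0.01)
  expect_lt(stats::fisher.test(matrix(c(9, 1, 1, 9), 2))$p.value, 0.01)
})

test_that("paired t test matches t.test and handles degenerate input", {
  set.seed(7)
  d <- rnorm(25, 0.4)
  ours <- paired_t(d)
  ref <- stats::t.test(d)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$df, 24L)

  z <- paired_t(rep(0, 10))
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
  expect_equal(paired_t(c(1, -1))$p_value, 1)
  expect_error(paired_t(1), "at least 2")
})

test_that("per-Myr rates reproduce the published duplication and rearrangement rates", {
  full <- rate_per_myr(32, 2.5)
  expect_equal(full$rate, 12.8)
  expect_equal(full$years_per_event, 78125)
  expect_equal(rate_per_myr(62, 2.5)$rate, 24.8)
  expect_equal(rate_per_myr(113, 0.5)$rate, 226)
  # additivity and the zero-count edge
  expect_equal(rate_per_myr(70, 2)$rate,
               rate_per_myr(30, 2)$rate + rate_per_myr(40, 2)$rate)
  z <- rate_per_myr(0, 2.5)
  expect_equal(z$rate, 0)
  expect_true(is.na(z$years_per_event))
  expect_error(rate_per_myr(5, 0), "positive")
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(prop_test_one_sample(33, 32, 0.5), "0 <= x <= n")
  expect_error(prop_test_one_sample(5, 32, 1.2), "inside")
  expect_error(binom_exact(-1, 10, 0.5), "0 <= x <= n")
})
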