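#' One-sample proportion test (normal approximation)
#'
#' Tests the observed proportion `x/n` against a null proportion `p0` with a
#' z statistic, optionally Yates-corrected. The continuity-corrected two-sided
#' variant is the default used throughout the duplication enrichment analyses
#' (e.g. X-linked duplication counts against the genome-wide proportion of
#' X-linked genes).
#'
#' The statistic is
#' \deqn{z = \mathrm{sign}(\hat p - p_0)\,
#'       \frac{|\hat p - p_0| - c/n}{\sqrt{p_0 (1-p_0)/n}}}
#' with \eqn{c = 1/2} when `continuity = TRUE` and 0 otherwise; the correction
#' is never allowed to overshoot past zero.
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param p0 Null proportion, strictly inside (0, 1).
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`.
#' @param continuity Apply the 1/(2n) continuity correction (default `TRUE`).
#' @return A list of class `prop_test_result` with fields `x`, `n`, `p0`,
#'   `estimate`, `z`, `p_value`, `alternative`, `continuity`.
#' @examples
#' prop_test_one_sample(43, 86, 0.158)
#' @export
prop_test_one_sample <- function(x, n, p0,
                                 alternative = c("two_sided", "greater", "less"),
                                 continuity = TRUE) {
  alternative <- match.arg(alternative)
  check_count_args(x, n)
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop("'p0' must lie strictly inside (0, 1)")
  phat <- x / n
  cc <- if (continuity) 0.5 / n else 0
  dev <- max(abs(phat - p0) - cc, 0)
  z <- sign(phat - p0) * dev / sqrt(p0 * (1 - p0) / n)
  structure(list(
    x = x, n = n, p0 = p0, estimate = phat, z = z,
    p_value = z_p_value(z, alternative),
    alternative = alternative, continuity = continuity
  ), class = "prop_test_result")
}

#' Two-sample proportion test (pooled z)
#'
#' Pooled-variance z test comparing `x1/n1` with `x2/n2`, with an optional
#' continuity correction of `(1/n1 + 1/n2)/2`.
#'
#' @inheritParams prop_test_one_sample
#' @param x1,n1 Successes and trials in the first sample.
#' @param x2,n2 Successes and trials in the second sample.
#' @return A `prop_test_result` list; `estimate` holds both sample proportions.
#' @export
prop_test_two_sample <- function(x1, n1, x2, n2,
                                 alternative = c("two_sided", "greater", "less"),
                                 continuity = TRUE) {
  alternative <- match.arg(alternative)
  check_count_args(x1, n1)
  check_count_args(x2, n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1)
    stop("degenerate pooled proportion (all successes or all failures)")
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  cc <- if (continuity) 0.5 * (1 / n1 + 1 / n2) else 0
  dev <- max(abs(p1 - p2) - cc, 0)
  z <- sign(p1 - p2) * dev / se
  structure(list(
    x = c(x1, x2), n = c(n1, n2), p0 = NA_real_,
    estimate = c(p1, p2), z = z,
    p_value = z_p_value(z, alternative),
    alternative = alternative, continuity = continuity
  ), class = "prop_test_result")
}

#' Exact binomial test p-value
#'
#' Exact tail sums of the binomial pmf; two-sided p-values use the
#' minimum-likelihood method (sum of all outcome probabilities not exceeding
#' that of the observed count, within a small relative tolerance). Serves as
#' the exact oracle behind the normal-approximation proportion tests.
#'
#' @inheritParams prop_test_one_sample
#' @return A single p-value in (0, 1].
#' @export
binom_exact <- function(x, n, p0,
                        alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_count_args(x, n)
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop("'p0' must lie strictly inside (0, 1)")
  pmf <- stats::dbinom(0:n, n, p0)
  p <- switch(alternative,
    greater   = sum(pmf[(x + 1L):(n + 1L)]),
    less      = sum(pmf[1L:(x + 1L)]),
    two_sided = sum(pmf[pmf <= pmf[x + 1L] * (1 + 1e-7)])
  )
  min(p, 1)
}

#' Paired t test on a vector of differences
#'
#' @param diffs Numeric vector of paired differences, length >= 2.
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`.
#' @return List of class `paired_t_result`: `n`, `mean_diff`, `sd_diff`, `t`,
#'   `df`, `p_value`, `degenerate`. Zero variance is flagged degenerate and
#'   reported with p = 1 rather than an infinite statistic.
#' @export
paired_t <- function(diffs, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 2L) stop("paired t test needs at least 2 differences")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) {
    t <- 0
    p <- 1
  } else {
    t <- m / (s / sqrt(n))
    p <- switch(alternative,
      two_sided = 2 * stats::pt(-abs(t), df = n - 1L),
      greater   = stats::pt(t, df = n - 1L, lower.tail = FALSE),
      less      = stats::pt(t, df = n - 1L)
    )
  }
  structure(list(
    n = n, mean_diff = m, sd_diff = s, t = t, df = n - 1L,
    p_value = p, alternative = alternative, degenerate = degenerate
  ), class = "paired_t_result")
}

#' Events per million years
#'
#' Converts an event count on a branch of known duration into a per-Myr rate
#' and a waiting time in years per event (e.g. 32 full-gene duplications over
#' the 2.5-Myr stem branch give 12.8 genes/Myr, one every 78,125 yr).
#'
#' @param count Non-negative event count.
#' @param myr Branch duration in millions of years (> 0).
#' @return List with `rate` (events/Myr) and `years_per_event` (`NA` when
#'   `count` is zero).
#' @export
rate_per_myr <- function(count, myr) {
  if (!is.numeric(myr) || length(myr) != 1L || myr <= 0)
    stop("'myr' must be a single positive number")
  if (!is.numeric(count) || length(count) != 1L || count < 0)
    stop("'count' must be a single non-negative number")
  list(
    rate = count / myr,
    years_per_event = if (count > 0) 1e6 * myr / count else NA_real_
  )
}

z_p_value <- function(z, alternative) {
  switch(alternative,
    two_sided = 2 * stats::pnorm(-abs(z)),
    greater   = stats::pnorm(z, lower.tail = FALSE),
    less      = stats::pnorm(z)
  )
}

check_count_args <- function(x, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x > n || x != round(x))
    stop("'x' must be an integer count with 0 <= x <= n")
  invisible(TRUE)
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat("Proportion test:", if (length(x$x) == 1L) "one-sample" else "two-sample",
      sprintf("(%s%s)\n", x$alternative, if (x$continuity) ", continuity-corrected" else ""))
  if (length(x$x) == 1L) {
    cat(sprintf("  x/n = %d/%d = %.4f  vs  p0 = %.4f\n", x$x, x$n, x$estimate, x$p0))
  } else {
    cat(sprintf("  %d/%d = %.4f  vs  %d/%d = %.4f\n",
                x$x[1], x$n[1], x$estimate[1], x$x[2], x$n[2], x$estimate[2]))
  }
  cat(sprintf("  z = %.4f, p = %.4g\n", x$z, x$p_value))
  invisible(x)
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("Paired t test (%s): n = %d, mean diff = %.4g, t = %.4f, df = %d, p = %.4g%s\n",
              x$alternative, x$n, x$mean_diff, x$t, x$df, x$p_value,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}
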