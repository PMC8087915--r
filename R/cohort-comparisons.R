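#' Test of equal proportions for CNA frequencies in two unmatched groups
#'
#' Pooled-variance chi-square test (two-sided, continuity-corrected by
#' default) of the event frequency in group A versus group B. Degenerate
#' tables with identical (or all-zero / all-one) pooled frequencies return
#' `p = 1`.
#'
#' @param count_A,n_A Event carriers and group size in group A.
#' @param count_B,n_B Same for group B.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return List of class `"region_test"`: `freq_A`, `freq_B`, `p`,
#'   `test_name`.
#' @export
#' @examples
#' two_proportion_test(12, 43, 1, 76)$p
two_proportion_test <- function(count_A, n_A, count_B, n_B, correct = TRUE) {
  assert_that(n_A >= 1 && n_B >= 1, "zero-size group")
  assert_that(count_A >= 0 && count_A <= n_A && count_B >= 0 && count_B <= n_B,
              "counts must lie in [0, n]")
  pooled <- (count_A + count_B) / (n_A + n_B)
  if (pooled %in% c(0, 1) || count_A / n_A == count_B / n_B) {
    p <- 1
  } else {
    p <- suppressWarnings(
      prop.test(c(count_A, count_B), c(n_A, n_B), correct = correct))$p.value
  }
  structure(list(freq_A = count_A / n_A, freq_B = count_B / n_B,
                 p = min(p, 1), test_name = "two_proportion"),
            class = "region_test")
}

#' McNemar's test for CNA frequency change in matched pairs
#'
#' Uses the discordant pair counts `b` (event in A only) and `c` (event in
#' B only): an exact two-sided binomial test when `b + c < 25`, otherwise
#' the continuity-corrected chi-square form. `b = c = 0` carries no
#' information and returns `p = 1`.
#'
#' @param b,c Discordant pair counts (A-only, B-only).
#' @return List of class `"region_test"` with `p` and `test_name`.
#' @export
#' @examples
#' mcnemar_test(5, 0)$p   # 2 * (1/2)^5 = 0.0625
mcnemar_test <- function(b, c) {
  assert_that(b >= 0 && c >= 0, "discordant counts must be >= 0")
  n_disc <- b + c
  if (n_disc == 0) {
    p <- 1
    test_name <- "mcnemar_exact"
  } else if (n_disc < 25) {
    p <- min(1, 2 * pbinom(min(b, c), n_disc, 0.5))
    test_name <- "mcnemar_exact"
  } else {
    tab <- matrix(c(0, c, b, 0), nrow = 2)
    p <- mcnemar.test(tab, correct = TRUE)$p.value
    test_name <- "mcnemar_chisq"
  }
  structure(list(freq_A = NA_real_, freq_B = NA_real_, p = p,
                 test_name = test_name),
            class = "region_test")
}

#' Genome-wide Fisher-exact scan of CNA frequency differences
#'
#' Per region, a two-tailed Fisher's exact test (hypergeometric tail
#' summation over tables with probability at most that of the observed
#' table) compares event carriage between two sample groups. Regions at or
#' below the unadjusted reporting threshold (default `p <= 0.005`) are
#' flagged; Benjamini-Hochberg adjusted p-values are reported alongside.
#'
#' @param matrix An [`event_matrix`][event_matrix()].
#' @param group_labels Factor/character vector over `matrix$samples` with
#'   exactly two levels.
#' @param direction `"gain"` or `"loss"`.
#' @param p_flag Unadjusted flagging threshold (default 0.005).
#' @return `data.frame`: region columns, `count_A`, `count_B`, `freq_A`,
#'   `freq_B`, `p`, `p_adj`, `flagged`.
#' @export
fisher_scan <- function(matrix, group_labels, direction = c("gain", "loss"),
                        p_flag = 0.005) {
  direction <- match.arg(direction)
  ev <- direction_events(matrix, direction)
  g <- as.factor(group_labels)
  assert_that(nlevels(g) == 2, "group_labels must have exactly two levels")
  assert_that(length(g) == ncol(ev), "group labels must match samples")
  assert_that(all(table(g) > 0), "one group is empty")
  a_idx <- g == levels(g)[1]
  n_A <- sum(a_idx); n_B <- sum(!a_idx)
  count_A <- rowSums(ev[, a_idx, drop = FALSE])
  count_B <- rowSums(ev[, !a_idx, drop = FALSE])
  p <- mapply(function(ca, cb) {
    fisher.test(matrix(c(ca, n_A - ca, cb, n_B - cb), nrow = 2))$p.value
  }, count_A, count_B)
  out <- cbind(matrix$regions,
               data.frame(count_A = count_A, count_B = count_B,
                          freq_A = count_A / n_A, freq_B = count_B / n_B,
                          p = pmin(p, 1), p_adj = p.adjust(pmin(p, 1), "BH")))
  out$flagged <- out$p <= p_flag
  attr(out, "groups") <- levels(g)
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjustment `p * m / rank` with cumulative-min monotonicity
#' enforcement, mapped back to the input order.
#'
#' @param p_values Vector of p-values in `(0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  assert_that(all(p_values > 0 & p_values <= 1), "p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Bonferroni per-test significance level
#'
#' @param alpha_family Family-wise error rate.
#' @param n_tests Number of tests (`>= 1`).
#' @return `alpha_family / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 29736)   # 1.7e-6 at two significant figures
bonferroni_threshold <- function(alpha_family, n_tests) {
  assert_that(n_tests >= 1, "n_tests must be >= 1")
  alpha_family / n_tests
}

#' Sample size for comparing two proportions
#'
#' Normal-approximation per-group sample size for a two-sided test of two
#' independent proportions, combining the pooled-variance term for the null
#' with the unpooled term for the alternative:
#' `n = (z_{a/2} * sqrt(2 p̄ q̄) + z_b * sqrt(p1 q1 + p2 q2))^2 / (p2 - p1)^2`,
#' optionally inflated by the Fleiss continuity correction
#' `n' = (n/4) * (1 + sqrt(1 + 4 / (n |p2 - p1|)))^2` (the default; small
#' event counts make the uncorrected approximation anticonservative).
#'
#' @param p1,p2 Event proportions in the two groups (`0 < p1 != p2 < 1`).
#' @param alpha Two-sided significance level.
#' @param power Target power (`1 - beta`).
#' @param correct Apply the Fleiss continuity correction (default `TRUE`).
#' @return List: `per_group` (ceiling of the chosen formula), `total`
#'   (`2 * per_group`), plus `per_group_uncorrected` / `total_uncorrected`.
#' @export
#' @examples
#' sample_size_two_prop(0.10, 0.40, alpha = 1.7e-6, power = 0.80)$total
sample_size_two_prop <- function(p1, p2, alpha = 0.05, power = 0.80,
                                 correct = TRUE) {
  assert_that(p1 > 0 && p1 < 1 && p2 > 0 && p2 < 1 && p1 != p2,
              "need 0 < p1 != p2 < 1")
  assert_that(alpha > 0 && alpha < 1 && power > 0 && power < 1,
              "alpha and power must lie in (0, 1)")
  d <- abs(p2 - p1)
  pbar <- (p1 + p2) / 2
  z_a <- qnorm(1 - alpha / 2)
  z_b <- qnorm(power)
  n <- (z_a * sqrt(2 * pbar * (1 - pbar)) +
        z_b * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / d^2
  n_corr <- n / 4 * (1 + sqrt(1 + 4 / (n * d)))^2
  chosen <- if (correct) n_corr else n
  list(per_group = ceiling(chosen), total = 2 * ceiling(chosen),
       per_group_uncorrected = ceiling(n), total_uncorrected = 2 * ceiling(n),
       continuity_correction = correct)
}
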