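test_that("two-proportion test handles identical and degenerate groups", {
  expect_equal(two_proportion_test(5, 20, 5, 20)$p, 1)
  expect_equal(two_proportion_test(0, 10, 0, 10)$p, 1)
  expect_equal(two_proportion_test(10, 10, 10, 10)$p, 1)
  expect_error(two_proportion_test(1, 0, 1, 5), "zero-size")
  # symmetry under group relabeling
  a <- two_proportion_test(12, 43, 1, 76)$p
  b <- two_proportion_test(1, 76, 12, 43)$p
  expect_equal(a, b)
})

test_that("two-proportion p agrees with a label-permutation Monte Carlo", {
  # permuting group labels with fixed margins makes the group-A event count
  # hypergeometric; 100,000 draws give the permutation reference
  set.seed(61)
  obs <- abs(12 / 43 - 1 / 76)
  draws <- rhyper(1e5, 43, 76, 13)
  p_mc <- mean(abs(draws / 43 - (13 - draws) / 76) >= obs - 1e-12)
  p_pkg <- two_proportion_test(12, 43, 1, 76)$p
  se <- sqrt(max(p_mc, p_pkg) * (1 - min(p_mc, p_pkg)) / 1e5)
  expect_lt(abs(p_pkg - p_mc), 3 * se)
})

test_that("McNemar exact and chi-square branches match their closed forms", {
  expect_equal(mcnemar_test(3, 3)$p, 1)
  expect_equal(mcnemar_test(5, 0)$p, 0.0625)   # 2 * (1/2)^5
  expect_equal(mcnemar_test(0, 0)$p, 1)
  expect_identical(mcnemar_test(5, 0)$test_name, "mcnemar_exact")
  # large discordance uses the continuity-corrected chi-square
  big <- mcnemar_test(20, 10)
  expect_identical(big$test_name, "mcnemar_chisq")
  expect_equal(big$p, mcnemar.test(matrix(c(0, 10, 20, 0), 2))$p.value)
  # symmetry
  expect_equal(mcnemar_test(2, 7)$p, mcnemar_test(7, 2)$p)
})

test_that("Fisher scan p-values equal exhaustive hypergeometric enumeration", {
  # [[2,0],[0,2]] -> 1/3 by enumerating the 3 tables with fixed margins
  g <- matrix(c(1, 1, 0, 0), 1, 4)
  em <- toy_event_matrix(g)
  labels <- c("A", "A", "B", "B")
  sc <- fisher_scan(em, labels, "gain")
  expect_equal(sc$p, 1 / 3)
  expect_equal(fisher_enum_p(2, 0, 0, 2), 1 / 3)
  # identical proportions -> p = 1
  g2 <- matrix(c(1, 0, 1, 0), 1, 4)
  expect_equal(fisher_scan(toy_event_matrix(g2), labels, "gain")$p, 1)
  # random tables with margins <= 12: package vs enumeration oracle
  set.seed(5)
  for (i in 1:25) {
    nA <- sample(2:12, 1); nB <- sample(2:12, 1)
    a <- rbinom(1, nA, 0.4); c <- rbinom(1, nB, 0.4)
    gm <- matrix(c(rep(1, a), rep(0, nA - a), rep(1, c), rep(0, nB - c)), 1)
    p_pkg <- fisher_scan(toy_event_matrix(gm),
                         rep(c("A", "B"), c(nA, nB)), "gain")$p
    expect_equal(p_pkg, fisher_enum_p(a, nA - a, c, nB - c), tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand step-up and is monotone", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_equal(adj, bh_by_hand(p))
  expect_true(all(adj >= p))
  expect_equal(max(adj), max(p))   # the largest p is unchanged
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("Bonferroni threshold is a plain division", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("two-proportion sample size reproduces the Fleiss worked numbers", {
  # classic textbook case: p1=.10, p2=.40, alpha=.05, power=.80
  res <- sample_size_two_prop(0.10, 0.40, alpha = 0.05, power = 0.80)
  expect_equal(res$per_group, 38)            # continuity-corrected
  expect_equal(res$per_group_uncorrected, 32)
  expect_error(sample_size_two_prop(0.2, 0.2), "p1 != p2")
})

test_that("required sample size shrinks with effect size and alpha", {
  n_small_d <- sample_size_two_prop(0.10, 0.30)$total
  n_big_d <- sample_size_two_prop(0.10, 0.50)$total
  expect_gt(n_small_d, n_big_d)
  n_strict <- sample_size_two_prop(0.10, 0.40, alpha = 1e-6)$total
  n_loose <- sample_size_two_prop(0.10, 0.40, alpha = 0.05)$total
  expect_gt(n_strict, n_loose)
  # power -> 0 limit: requirement collapses monotonically
  pows <- c(0.8, 0.5, 0.2, 0.05)
  ns <- sapply(pows, function(pw)
    sample_size_two_prop(0.10, 0.40, power = pw)$total)
  expect_true(all(diff(ns) <= 0))
})

test_that("null Fisher scans reject near the nominal rate", {
  set.seed(23)
  nr <- 1000
  g <- matrix(rbinom(nr * 60, 1, 0.10), nr, 60)
  em <- toy_event_matrix(g)
  sc <- fisher_scan(em, rep(c("A", "B"), each = 30), "gain")
  n_hits <- sum(sc$p <= 0.005)
  # Fisher's exact test is conservative: stay within the binomial 99% band
  expect_lte(n_hits, qbinom(0.995, nr, 0.005))
  # BH thresholding controls the count of null discoveries
  expect_lte(sum(sc$p_adj <= 0.05), n_hits)
})
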