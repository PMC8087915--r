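test_that("log-rank statistic matches hand tabulation and survdiff", {
  # A events at 1 and 3, B events at 2 and 4: O-E = 2/3, V = 13/18
  st <- logrank_statistic(c(1, 3, 2, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(st, 8 / 13)
  sd_fit <- survival::survdiff(
    survival::Surv(c(1, 3, 2, 4), rep(1, 4)) ~ c("A", "A", "B", "B"))
  expect_equal(st, unname(sd_fit$chisq))
  # identical groups (duplicated data) -> statistic 0
  expect_equal(logrank_statistic(c(1, 2, 3, 1, 2, 3), rep(1, 6),
                                 rep(c("A", "B"), each = 3)), 0)
  # label swap invariance
  tm <- c(2, 5, 3, 8, 1, 9); ev <- c(1, 0, 1, 1, 1, 0)
  g <- c("A", "B", "A", "B", "B", "A")
  expect_equal(logrank_statistic(tm, ev, g),
               logrank_statistic(tm, ev, ifelse(g == "A", "B", "A")))
  # fully censored group contributes no information
  expect_equal(logrank_statistic(c(1, 2, 3, 4), c(0, 0, 1, 1),
                                 c("A", "A", "B", "B")), 0)
  expect_error(logrank_statistic(c(1, 2), c(0, 0), c("A", "B")), "no events")
})

test_that("log-rank agrees with survdiff on ties and censoring", {
  set.seed(31)
  for (i in 1:10) {
    n <- 30
    tm <- round(rexp(n, 0.1), 0) + 1   # forces ties
    ev <- rbinom(n, 1, 0.7)
    g <- rep(c("A", "B"), each = 15)
    if (sum(ev) == 0) next
    st <- logrank_statistic(tm, ev, g)
    ref <- survival::survdiff(survival::Surv(tm, ev) ~ g)$chisq
    expect_equal(st, unname(ref), tolerance = 1e-10)
  }
})

test_that("permutation scan matches exact enumeration at n = 6", {
  tm <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 1, 0, 1, 1, 1)
  carrier <- c(1, 1, 1, 0, 0, 0)
  p_exact <- logrank_perm_exact(tm, ev, carrier == 1)
  em <- toy_event_matrix(matrix(carrier, 1, 6))
  sc <- permutation_scan(em, tm, ev, "gain", B = 10000, alpha_perm = 0.05,
                         min_group = 3, seed = 12)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(sc$p_perm - p_exact), 3 * se + 2e-4)
})

test_that("scan handles degenerate regions and reproduces under a seed", {
  tm <- rexp(12, 0.1) + 0.1; ev <- rep(1, 12)
  g_all <- matrix(1, 1, 12)          # carried by every sample: untested
  sc <- permutation_scan(toy_event_matrix(g_all), tm, ev, "gain",
                         B = 199, alpha_perm = 0.05, seed = 1)
  expect_false(sc$tested)
  expect_true(is.na(sc$p_perm))
  g <- matrix(rep(c(1, 0), each = 6), 1, 12)
  s1 <- permutation_scan(toy_event_matrix(g), tm, ev, "gain", B = 199,
                         alpha_perm = 0.05, seed = 42)
  s2 <- permutation_scan(toy_event_matrix(g), tm, ev, "gain", B = 199,
                         alpha_perm = 0.05, seed = 42)
  expect_identical(s1, s2)
  expect_gte(s1$p_perm, 1 / 200)
  expect_lte(s1$p_perm, 1)
  expect_error(permutation_scan(toy_event_matrix(g), tm, ev, "gain",
                                B = 50, alpha_perm = 0.005, seed = 1),
               "unreachable")
})

test_that("permutation p agrees with the chi-square reference at moderate n", {
  set.seed(19)
  n <- 40
  tm <- rexp(n, 0.08); ev <- rbinom(n, 1, 0.8)
  carrier <- rbinom(n, 1, 0.4)
  em <- toy_event_matrix(matrix(carrier, 1, n))
  sc <- permutation_scan(em, tm, ev, "gain", B = 1999, alpha_perm = 0.005,
                         seed = 3)
  p_chisq <- pchisq(sc$observed_stat, 1, lower.tail = FALSE)
  expect_lt(abs(sc$p_perm - p_chisq), 0.05)
})

test_that("Kaplan-Meier estimate matches product-limit closed forms", {
  # all events at 1, 2, 3
  k1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k1$steps$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(k1$median, 2)
  # all censored: flat at 1, median undefined
  k2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(k2$steps$surv == 1))
  expect_true(is.na(k2$median))
  # mixed set {1, 2+, 3, 3+}: S(1) = 3/4, S(3) = 3/4 * 1/2 = 3/8
  k3 <- km_estimate(c(1, 2, 3, 3), c(1, 0, 1, 0))
  expect_equal(k3$steps$surv[k3$steps$time == 1], 0.75)
  expect_equal(k3$steps$surv[k3$steps$time == 3], 0.375)
  expect_equal(k3$median, 3)
  # survfit cross-check on a random censored sample
  set.seed(8)
  tm <- rexp(25, 0.2); ev <- rbinom(25, 1, 0.6)
  k4 <- km_estimate(tm, ev)
  fit <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  expect_equal(k4$steps$surv, fit$surv)
  # monotone non-increasing, S(0) = 1 implied by first step <= 1
  expect_true(all(diff(k4$steps$surv) <= 1e-12))
  expect_lte(k4$steps$surv[1], 1)
})
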