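test_that("log2 ratios honor identity, scaling, and planted-shift contracts", {
  tg <- toy_targets(40)
  # tumor identical to normal -> all zero
  r0 <- compute_log2_ratio(rep(100, 40), rep(100, 40), tg)
  expect_equal(r0$log2_ratio, rep(0, 40))
  # uniform doubling is removed by total scaling (ploidy unidentifiable)
  r2 <- compute_log2_ratio(rep(200, 40), rep(100, 40), tg)
  expect_equal(r2$log2_ratio, rep(0, 40))
  # one region at twice the background ratio: in-region ~1, elsewhere ~0
  tum <- rep(1000, 40); tum[11:20] <- 2000
  r <- compute_log2_ratio(tum, rep(1000, 40), tg)
  expect_lt(max(abs(r$log2_ratio[-(11:20)])), 1e-9)
  expect_lt(abs(mean(r$log2_ratio[11:20]) - 1.0), 0.01)
  expect_lt(abs(median(r$log2_ratio)), 1e-9)   # median-centered
})

test_that("log2 ratio rejects malformed input and drops sex chromosomes", {
  tg <- toy_targets(10)
  expect_error(compute_log2_ratio(rep(1, 9), rep(1, 10), tg), "length")
  expect_error(compute_log2_ratio(rep(1, 10), rep(0, 10), tg), "all-zero")
  tg2 <- toy_targets(10, chroms = c("chr1", "chrX"))
  r <- compute_log2_ratio(rep(100, 20), rep(100, 20), tg2)
  expect_false(any(r$chrom == "chrX"))
  expect_equal(nrow(r), 10)
})

test_that("pooled reference averages total-scaled normals", {
  # normals {(10,20),(30,20)}: totals 30 and 50, common total 40
  # scaled: (13.333, 26.667) and (24, 16) -> means (18.667, 21.333)
  ref <- build_pooled_reference(cbind(c(10, 20), c(30, 20)))
  expect_equal(ref, c(56 / 3, 64 / 3))
  # identical normals -> reference equals either input
  ref2 <- build_pooled_reference(cbind(c(5, 10), c(5, 10)))
  expect_equal(ref2, c(5, 10))
  expect_error(build_pooled_reference(cbind(c(1, 2))), "at least 2")
})

test_that("tumor vs pooled reference from other samples yields a finite track", {
  cfg <- cohort_config(n_pre = 4, n_post = 0, targets_per_chrom = 20,
                       n_chrom = 1, n_genes = 5, seed = 2)
  coh <- simulate_cohort(cfg)
  pool <- build_pooled_reference(coh$normal_counts[, -1])
  r <- compute_log2_ratio(coh$tumor_counts[, 1], pool, coh$targets,
                          reference_kind = "pooled")
  expect_true(all(is.finite(r$log2_ratio)))
  expect_identical(attr(r, "reference_kind"), "pooled")
})

test_that("segmentation recovers exact and noisy change points", {
  # constant track -> one segment per chromosome
  sg0 <- segment_ratios(toy_track(rep(0.3, 60), chroms = c("chr1", "chr2")),
                        seed = 1)
  expect_equal(nrow(sg0), 2)
  # noiseless two-level step: breakpoint exactly at index 20, means 0 and 1
  sg1 <- segment_ratios(toy_track(rep(c(0, 1), each = 20)), seed = 1)
  expect_equal(nrow(sg1), 2)
  expect_equal(sg1$last_target[1], 20)
  expect_equal(sg1$mean_log2, c(0, 1))
  expect_error(segment_ratios(toy_track(c(rep(0, 10), NA, rep(0, 10)))),
               "non-finite")
})

test_that("first split matches an exhaustive single-split t-statistic search", {
  set.seed(7)
  x <- c(rnorm(30, 0, 0.1), rnorm(20, 0.6, 0.1))
  # independent oracle: score every admissible cut with a pooled-variance t
  tstats <- sapply(3:47, function(k) {
    abs(unname(t.test(x[1:k], x[(k + 1):50], var.equal = TRUE)$statistic))
  })
  oracle_cut <- (3:47)[which.max(tstats)]
  sg <- segment_ratios(toy_track(x), seed = 3)
  expect_equal(nrow(sg), 2)
  expect_equal(sg$last_target[1], oracle_cut)
})

test_that("re-segmenting segment means reproduces the breakpoints", {
  set.seed(11)
  x <- c(rnorm(25, -0.5, 0.05), rnorm(25, 0.3, 0.05))
  sg <- segment_ratios(toy_track(x), seed = 5)
  means <- rep(sg$mean_log2, sg$n_targets)
  sg2 <- segment_ratios(toy_track(means), seed = 6)
  expect_equal(sg2$last_target, sg$last_target)
  expect_equal(sg2$mean_log2, sg$mean_log2, tolerance = 1e-12)
})

test_that("planted boundaries are recovered within two targets at low noise", {
  hits <- 0; total <- 0
  for (sd in 1:5) {
    tr <- truth_region("chr1", 30000, 70000, "gain", 0.4,
                       freq_pre = 1, freq_post = 1)
    cfg <- cohort_config(n_pre = 4, n_post = 0, targets_per_chrom = 100,
                         n_chrom = 1, target_bp = 1000L, truth_regions = tr,
                         depth_dispersion = 2e-4, n_genes = 5, seed = sd)
    coh <- simulate_cohort(cfg)
    for (s in colnames(coh$tumor_counts)) {
      track <- compute_log2_ratio(coh$tumor_counts[, s],
                                  coh$normal_counts[, s], coh$targets,
                                  sample_id = s)
      sg <- segment_ratios(track, seed = sd + 100)
      bnd <- c(sg$first_target[-1] - 1)
      total <- total + 2
      hits <- hits + any(abs(bnd - 30) <= 2) + any(abs(bnd - 70) <= 2)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("calls follow the inclusive ordered thresholds", {
  sg <- toy_track(rep(0, 5))   # placeholder track
  seg <- data.frame(chrom = "chr1", start = 0:4 * 10, end = 1:5 * 10,
                    n_targets = 5,
                    mean_log2 = c(0, 0.2, -1.3, -0.2, 1.0))
  called <- call_segments(seg)
  expect_equal(as.character(called$call),
               c("neutral", "gain", "homozygous_loss", "loss", "high_gain"))
  expect_error(call_segments(seg, thresholds = c(hom_loss = 0.5, loss = -0.2,
                                                 gain = 0.2, high_gain = 1)),
               "ordered")
})

test_that("qc metrics match closed forms", {
  expect_equal(qc_metrics(toy_track(rep(0.2, 30)))$dlrs, 0)
  h <- 0.35
  alt <- toy_track(rep(c(0, h), 20))
  expect_equal(qc_metrics(alt)$dlrs, h / sqrt(2))
  # all-neutral segmentation -> zero fraction altered
  sg <- call_segments(data.frame(chrom = "chr1", start = 0, end = 100,
                                 n_targets = 10, mean_log2 = 0))
  expect_equal(qc_metrics(toy_track(rep(0, 10)), sg)$fraction_genome_altered, 0)
  # single-target chromosomes contribute no adjacent pairs
  tk <- toy_track(c(rep(0, 10), 5))
  tk$chrom <- c(rep("chr1", 10), "chr2")
  expect_equal(qc_metrics(tk)$dlrs, 0)
})

test_that("dlrs decreases as depth dispersion shrinks", {
  dlrs_at <- function(phi) {
    mean(sapply(1:3, function(sd) {
      cfg <- cohort_config(n_pre = 2, n_post = 0, targets_per_chrom = 60,
                           n_chrom = 1, depth_dispersion = phi, n_genes = 5,
                           seed = sd)
      coh <- simulate_cohort(cfg)
      mean(sapply(colnames(coh$tumor_counts), function(s) {
        qc_metrics(compute_log2_ratio(coh$tumor_counts[, s],
                                      coh$normal_counts[, s],
                                      coh$targets))$dlrs
      }))
    }))
  }
  d <- sapply(c(0.02, 0.002, 0), dlrs_at)
  expect_true(all(diff(d) < 0))
})
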