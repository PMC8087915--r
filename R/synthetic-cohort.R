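#' Define a planted ("truth") copy-number region for simulation
#'
#' A truth region is an autosomal interval carried by a configurable fraction
#' of pre- and post-treatment samples, with a known log2 coverage shift, a
#' multiplicative effect on the progression hazard, and a dosage multiplier
#' on the expression of genes inside the interval.
#'
#' @param chrom Autosome label (e.g. `"chr1"`). Sex chromosomes are rejected.
#' @param start,end Interval coordinates, 0-based half-open.
#' @param direction `"gain"` or `"loss"`.
#' @param log2_shift Expected segment log2 ratio for carriers; its sign must
#'   match `direction` (e.g. `+0.58` for one extra copy over two).
#' @param freq_pre,freq_post Carrier probability among pre-/post-treatment
#'   samples, each in `[0, 1]`.
#' @param hazard_ratio Multiplicative effect on the progression hazard for
#'   carriers (`1` = no effect; must be `> 0`).
#' @param expr_dosage Multiplier applied to the mean expression of genes
#'   inside the interval for carriers (`> 0`).
#' @return A one-row `data.frame` describing the region.
#' @export
#' @examples
#' truth_region("chr2", 1e6, 2e6, "gain", 0.58, freq_pre = 0.02, freq_post = 0.3)
truth_region <- function(chrom, start, end, direction = c("gain", "loss"),
                         log2_shift, freq_pre = 0, freq_post = 0,
                         hazard_ratio = 1, expr_dosage = 1) {
  direction <- match.arg(direction)
  assert_that(!is_sex_chrom(chrom), "truth regions must be autosomal")
  assert_that(start < end, "truth region: start must be < end")
  assert_that(sign(log2_shift) == ifelse(direction == "gain", 1, -1),
              "log2_shift sign must match direction")
  assert_that(freq_pre >= 0 && freq_pre <= 1 && freq_post >= 0 && freq_post <= 1,
              "carrier frequencies must lie in [0, 1]")
  assert_that(hazard_ratio > 0 && expr_dosage > 0,
              "hazard_ratio and expr_dosage must be > 0")
  data.frame(chrom = chrom, start = start, end = end, direction = direction,
             log2_shift = log2_shift, freq_pre = freq_pre, freq_post = freq_post,
             hazard_ratio = hazard_ratio, expr_dosage = expr_dosage,
             stringsAsFactors = FALSE)
}

#' Configure a synthetic longitudinal cohort
#'
#' Defaults emulate the study design the package targets: 97 pre-treatment
#' and 43 post-treatment liver-metastasis samples, a baseline progression
#' hazard matching a 9.7-month median PFS, and moderately overdispersed
#' exome coverage.
#'
#' @param n_pre,n_post Number of pre-/post-treatment samples.
#' @param targets_per_chrom,n_chrom Size of the synthetic exome target map.
#' @param target_bp Width of each target in bp (targets tile each chromosome).
#' @param mean_depth Expected read count per target in the normal. Targets
#'   emulate coverage windows binned to hold thousands of reads, as matched
#'   tumor/normal pseudo-CGH processing does; the default, together with
#'   `depth_dispersion`, puts the per-sample DLRS noise metric near 0.04.
#' @param depth_dispersion Negative-binomial dispersion of counts
#'   (variance = mu + dispersion * mu^2); `0` gives Poisson counts.
#' @param truth_regions `data.frame` of planted regions from [truth_region()]
#'   (rbind rows for several); may be empty for a null cohort.
#' @param baseline_hazard Exponential progression rate per month
#'   (default `log(2)/9.7`, i.e. median PFS 9.7 months).
#' @param censor_rate Rate of the independent exponential censoring process.
#' @param nb_dispersion Expression-count dispersion.
#' @param n_genes Number of simulated genes (placed uniformly over the map).
#' @param gene_length_range Exonic length range in bp.
#' @param seed Integer seed; recorded in every output.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_pre = 97, n_post = 43,
                          targets_per_chrom = 120, n_chrom = 4,
                          target_bp = 10000L,
                          mean_depth = 5000, depth_dispersion = 7e-4,
                          truth_regions = NULL,
                          baseline_hazard = log(2) / 9.7, censor_rate = 0.02,
                          nb_dispersion = 0.1, n_genes = 400,
                          gene_length_range = c(500, 5000), seed = 1L) {
  assert_that(n_pre + n_post >= 1, "empty cohort")
  assert_that(n_pre >= 0 && n_post >= 0 && targets_per_chrom > 0 && n_chrom > 0,
              "all counts must be positive")
  assert_that(mean_depth > 0, "non-positive mean depth")
  assert_that(depth_dispersion >= 0 && nb_dispersion >= 0,
              "dispersions must be >= 0")
  assert_that(baseline_hazard > 0 && censor_rate >= 0,
              "hazard rates must be positive")
  if (is.null(truth_regions)) {
    truth_regions <- truth_region("chr1", 0, 1, "gain", 1)[0, ]
  }
  if (nrow(truth_regions) > 1) {
    o <- order(truth_regions$chrom, truth_regions$start)
    tr <- truth_regions[o, ]
    same <- tr$chrom[-1] == tr$chrom[-nrow(tr)]
    assert_that(all(!same | tr$start[-1] >= tr$end[-nrow(tr)]),
                "truth regions must not overlap")
  }
  structure(list(n_pre = n_pre, n_post = n_post,
                 targets_per_chrom = targets_per_chrom, n_chrom = n_chrom,
                 target_bp = as.integer(target_bp),
                 mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 truth_regions = truth_regions,
                 baseline_hazard = baseline_hazard, censor_rate = censor_rate,
                 nb_dispersion = nb_dispersion, n_genes = n_genes,
                 gene_length_range = gene_length_range,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# NB draw that degrades to Poisson as dispersion -> 0.
rnb <- function(n, mu, dispersion) {
  if (dispersion <= 1e-12) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate a complete longitudinal cohort with known ground truth
#'
#' Draws, per sample: carrier status for each truth region
#' (timepoint-specific frequency), matched tumor/normal per-target exome
#' counts (tumor mean multiplied by `2^log2_shift` inside carried regions),
#' a progression-free-survival time (exponential with rate
#' `baseline_hazard * prod(hazard_ratio)` over carried regions, independently
#' censored), and gene-level expression counts (negative binomial, carrier
#' genes scaled by `expr_dosage`). Truth labels are returned in a separate
#' element, never embedded in the analysis inputs.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"cna_cohort"` with elements `targets`,
#'   `tumor_counts`, `normal_counts` (targets x samples), `clinical`,
#'   `genes`, `expr_counts` (genes x samples), `truth` (list with
#'   `regions` and the regions x samples `carriers` 0/1 matrix), `config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_pre = 6, n_post = 4, targets_per_chrom = 30,
#'                      n_chrom = 2, n_genes = 40, seed = 7)
#' coh <- simulate_cohort(cfg)
#' dim(coh$tumor_counts)
simulate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  set.seed(config$seed)
  n <- config$n_pre + config$n_post
  assert_that(n >= 1, "empty cohort")

  chroms <- paste0("chr", seq_len(config$n_chrom))
  tpc <- config$targets_per_chrom
  targets <- data.frame(
    chrom = rep(chroms, each = tpc),
    start = rep((seq_len(tpc) - 1L) * config$target_bp, times = config$n_chrom),
    end   = rep(seq_len(tpc) * config$target_bp, times = config$n_chrom),
    stringsAsFactors = FALSE)
  targets$target_id <- sprintf("%s:%d-%d", targets$chrom, targets$start, targets$end)
  nt <- nrow(targets)

  sample_id <- c(sprintf("PRE%03d", seq_len(config$n_pre)),
                 sprintf("POST%03d", seq_len(config$n_post)))
  timepoint <- rep(c("pre", "post"), c(config$n_pre, config$n_post))

  tr <- config$truth_regions
  nr <- nrow(tr)
  if (nr > 0) rownames(tr) <- sprintf("R%02d", seq_len(nr))
  carriers <- matrix(0L, nrow = nr, ncol = n,
                     dimnames = list(rownames(tr), sample_id))
  if (nr > 0) {
    for (r in seq_len(nr)) {
      p <- ifelse(timepoint == "pre", tr$freq_pre[r], tr$freq_post[r])
      carriers[r, ] <- rbinom(n, 1L, p)
    }
  }

  # per-target expected tumor/normal depth; region membership by overlap
  region_targets <- lapply(seq_len(nr), function(r) {
    which(targets$chrom == tr$chrom[r] &
          targets$start < tr$end[r] & targets$end > tr$start[r])
  })
  normal_counts <- matrix(rnb(nt * n, config$mean_depth, config$depth_dispersion),
                          nrow = nt, dimnames = list(targets$target_id, sample_id))
  mu_t <- matrix(config$mean_depth, nrow = nt, ncol = n)
  if (nr > 0) {
    for (r in seq_len(nr)) {
      idx <- region_targets[[r]]
      if (length(idx)) {
        cc <- which(carriers[r, ] == 1L)
        mu_t[idx, cc] <- mu_t[idx, cc] * 2^tr$log2_shift[r]
      }
    }
  }
  tumor_counts <- matrix(rnb(nt * n, as.vector(mu_t), config$depth_dispersion),
                         nrow = nt, dimnames = list(targets$target_id, sample_id))

  # survival: exponential progression hazard scaled by carried regions
  hr <- if (nr > 0) {
    apply(carriers, 2, function(cs) prod(tr$hazard_ratio[cs == 1L]))
  } else rep(1, n)
  t_prog <- rexp(n, rate = config$baseline_hazard * hr)
  t_cens <- if (config$censor_rate > 0) rexp(n, rate = config$censor_rate) else rep(Inf, n)
  pfs_months <- pmin(t_prog, t_cens)
  progression <- as.integer(t_prog <= t_cens)

  clinical <- data.frame(
    sample_id = sample_id,
    patient_id = sprintf("P%03d", seq_len(n)),
    timepoint = timepoint,
    pfs_months = round(pfs_months, 3),
    progression = progression,
    bevacizumab = rbinom(n, 1L, 0.70),
    regimen = sample(c("oxaliplatin-based", "irinotecan-based", "other"), n,
                     replace = TRUE, prob = c(0.68, 0.22, 0.10)),
    stringsAsFactors = FALSE)

  # expression: genes placed uniformly over the map, NB counts with dosage
  genome_bp <- config$n_chrom * tpc * config$target_bp
  glen <- round(runif(config$n_genes, config$gene_length_range[1],
                      config$gene_length_range[2]))
  gpos <- sort(round(runif(config$n_genes, 0, genome_bp - max(glen))))
  gchrom_idx <- pmin(gpos %/% (tpc * config$target_bp) + 1, config$n_chrom)
  gstart <- gpos - (gchrom_idx - 1) * tpc * config$target_bp
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(config$n_genes)),
                      chrom = chroms[gchrom_idx],
                      start = gstart, end = gstart + glen, length = glen,
                      stringsAsFactors = FALSE)
  base_mean <- exp(rnorm(config$n_genes, log(100), 1))
  mu_e <- matrix(base_mean, nrow = config$n_genes, ncol = n)
  if (nr > 0) {
    for (r in seq_len(nr)) {
      gidx <- which(genes$chrom == tr$chrom[r] &
                    genes$start < tr$end[r] & genes$end > tr$start[r])
      if (length(gidx)) {
        cc <- which(carriers[r, ] == 1L)
        mu_e[gidx, cc] <- mu_e[gidx, cc] * tr$expr_dosage[r]
      }
    }
  }
  sf <- exp(rnorm(n, 0, 0.1))
  expr_counts <- matrix(rnb(config$n_genes * n, as.vector(t(t(mu_e) * sf)),
                            config$nb_dispersion),
                        nrow = config$n_genes,
                        dimnames = list(genes$gene_id, sample_id))

  structure(list(targets = targets, tumor_counts = tumor_counts,
                 normal_counts = normal_counts, clinical = clinical,
                 genes = genes, expr_counts = expr_counts,
                 truth = list(regions = tr, carriers = carriers),
                 config = config, seed = config$seed),
            class = "cna_cohort")
}

#' @export
print.cna_cohort <- function(x, ...) {
  cat("Synthetic CNA cohort\n")
  cat(sprintf("  samples: %d pre + %d post; targets: %d; genes: %d\n",
              x$config$n_pre, x$config$n_post, nrow(x$targets), nrow(x$genes)))
  cat(sprintf("  planted regions: %d; seed: %d\n",
              nrow(x$truth$regions), x$seed))
  invisible(x)
}

#' Generate a lesion longest-diameter series of a requested response class
#'
#' Produces an ordered (week, diameter) series whose objective-response
#' classification under [classify_lesion()] is the requested class:
#' IRES (>= 20% growth by the first 8-week evaluation), PR (>= 30% shrinkage
#' from baseline), SD (neither), or ARES (a PR/SD phase followed by >= 20%
#' regrowth over the nadir).
#'
#' @param class One of `"IRES"`, `"PR"`, `"SD"`, `"ARES"`.
#' @param baseline_mm Baseline longest diameter in mm (`> 0`).
#' @param seed Integer seed.
#' @param eval_week First evaluation week (default 8).
#' @return A `data.frame` with columns `week` and `diameter_mm`.
#' @export
#' @examples
#' s <- generate_lesion_series("ARES", 50, seed = 1)
#' classify_lesion(s)$class
generate_lesion_series <- function(class = c("IRES", "PR", "SD", "ARES"),
                                   baseline_mm, seed = 1L, eval_week = 8) {
  class <- match.arg(class)
  assert_that(is.numeric(baseline_mm) && baseline_mm > 0, "baseline_mm must be > 0")
  set.seed(as.integer(seed))
  wk <- c(0, eval_week, 2 * eval_week, 3 * eval_week)
  b <- baseline_mm
  d <- switch(class,
    IRES = b * c(1, runif(1, 1.21, 1.60), runif(1, 1.30, 1.90), runif(1, 1.40, 2.2)),
    PR = {
      nadir <- runif(1, 0.35, 0.695)
      mid <- runif(1, max(nadir, 0.72), 1.05)
      # non-increasing after week 8: never regrows over the running nadir
      b * c(1, mid, runif(1, nadir, mid), nadir)
    },
    SD = {
      # stays above 70% of baseline and below 120% of the running nadir
      d2 <- runif(1, 0.85, 1.10)
      lo <- 0.71; hi <- min(1.19, 1.195 * d2)
      d3 <- runif(1, lo, hi)
      d4 <- runif(1, lo, min(1.19, 1.195 * min(d2, d3)))
      b * c(1, d2, d3, d4)
    },
    ARES = {
      nadir <- runif(1, 0.45, 0.80)   # PR or SD phase first
      first <- runif(1, max(nadir, 0.75), 1.05)
      b * c(1, first, nadir, nadir * runif(1, 1.21, 1.60))
    })
  data.frame(week = wk, diameter_mm = d)
}
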