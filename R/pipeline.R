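#' Run the full copy-number analysis pipeline on a cohort
#'
#' Sequences the analysis stages on a simulated or ingested cohort:
#' matched log2 ratios and segmentation per sample, five-level calling,
#' QC, event-matrix construction, GISTIC-style recurrence per direction,
#' pre-versus-post frequency comparisons (test of equal proportions and
#' Fisher scan), the permutation log-rank survival scan on pre-treatment
#' samples, and transcriptional concordance for the significant regions.
#' Stages can be skipped; all intermediates are plain `data.frame`s.
#'
#' @param cohort A [`cna_cohort`][simulate_cohort()] (or a list with the
#'   same elements assembled from files via the readers in this package).
#' @param seed Integer seed driving every stochastic stage.
#' @param segmentation Parameters passed to [segment_ratios()].
#' @param thresholds Call thresholds for [call_segments()].
#' @param recurrence_B,scan_B Permutation counts for
#'   [recurrence_significance()] and [permutation_scan()].
#' @param fisher_p_flag Unadjusted Fisher flagging threshold.
#' @param alpha_perm Survival-scan reporting threshold.
#' @param min_group Minimum group size per tested region in the scan.
#' @param stages Character subset of
#'   `c("calling", "recurrence", "comparison", "survival", "expression")`.
#' @return List of class `"cna_report"` with per-stage tables and a
#'   `provenance` record (seed, config hash, stage row counts).
#' @export
run_pipeline <- function(cohort, seed = 1L,
                         segmentation = list(alpha_split = 0.01, n_perm = 200,
                                             min_targets = 3, merge_delta = 0.1),
                         thresholds = c(hom_loss = -1, loss = -0.2,
                                        gain = 0.2, high_gain = 1),
                         recurrence_B = 499, scan_B = 999,
                         fisher_p_flag = 0.005, alpha_perm = 0.005,
                         min_group = 3,
                         stages = c("calling", "recurrence", "comparison",
                                    "survival", "expression")) {
  assert_that(!is.null(cohort$clinical) && nrow(cohort$clinical) > 0,
              "empty clinical table")
  assert_that(!is.null(cohort$tumor_counts) && !is.null(cohort$normal_counts),
              "cohort must carry tumor and normal counts")
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list()
  samples <- cohort$clinical$sample_id

  # --- CNA calling ---------------------------------------------------------
  assert_that("calling" %in% stages, "the calling stage cannot be skipped")
  segs <- list()
  qc <- list()
  for (k in seq_along(samples)) {
    s <- samples[k]
    track <- compute_log2_ratio(cohort$tumor_counts[, s],
                                cohort$normal_counts[, s],
                                cohort$targets, sample_id = s)
    sg <- segment_ratios(track,
                         alpha_split = segmentation$alpha_split,
                         n_perm = segmentation$n_perm,
                         min_targets = segmentation$min_targets,
                         merge_delta = segmentation$merge_delta,
                         seed = derive_seed(seed, k))
    sg <- call_segments(sg, thresholds)
    segs[[s]] <- sg
    q <- qc_metrics(track, sg)
    qc[[s]] <- data.frame(sample_id = s, dlrs = q$dlrs,
                          n_segments = q$n_segments,
                          fraction_genome_altered = q$fraction_genome_altered)
  }
  report$qc <- do.call(rbind, qc)
  rownames(report$qc) <- NULL
  em <- build_event_matrix(segs)
  report$event_matrix <- em
  report$segments <- do.call(rbind, lapply(names(segs), function(s) {
    d <- as.data.frame(segs[[s]]); d$sample_id <- s; d
  }))

  # --- recurrence ----------------------------------------------------------
  if ("recurrence" %in% stages) {
    report$recurrence <- do.call(rbind, lapply(c("gain", "loss"), function(dir) {
      recurrence_significance(em, dir, B = recurrence_B,
                              seed = derive_seed(seed, 101L))
    }))
  }

  # --- pre vs post comparison ---------------------------------------------
  if ("comparison" %in% stages) {
    tp <- cohort$clinical$timepoint
    if (length(unique(tp)) == 2) {
      grp <- factor(tp, levels = c("post", "pre"))
      report$fisher <- do.call(rbind, lapply(c("gain", "loss"), function(dir) {
        out <- fisher_scan(em, grp, dir, p_flag = fisher_p_flag)
        out$direction <- dir
        out
      }))
      ev_by_dir <- list(gain = em$gain, loss = em$loss)
      report$prop_test <- do.call(rbind, lapply(c("gain", "loss"), function(dir) {
        ev <- ev_by_dir[[dir]]
        res <- lapply(seq_len(nrow(ev)), function(r) {
          tt <- two_proportion_test(sum(ev[r, grp == "post"]), sum(grp == "post"),
                                    sum(ev[r, grp == "pre"]), sum(grp == "pre"))
          data.frame(direction = dir, freq_post = tt$freq_A,
                     freq_pre = tt$freq_B, p = tt$p)
        })
        cbind(em$regions, do.call(rbind, res))
      }))
      report$prop_test$p_adj <- p.adjust(report$prop_test$p, "BH")
    }
  }

  # --- survival scan (pre-treatment samples) -------------------------------
  if ("survival" %in% stages) {
    cl <- cohort$clinical
    pre_idx <- cl$timepoint == "pre"
    if (sum(pre_idx) >= 2 * min_group && sum(cl$progression[pre_idx]) >= 1) {
      em_pre <- event_matrix(em$regions,
                             em$gain[, pre_idx, drop = FALSE],
                             em$loss[, pre_idx, drop = FALSE],
                             em$amplitude[, pre_idx, drop = FALSE])
      report$survival <- do.call(rbind, lapply(c("gain", "loss"), function(dir) {
        out <- permutation_scan(em_pre, cl$pfs_months[pre_idx],
                                cl$progression[pre_idx], dir,
                                B = scan_B, alpha_perm = alpha_perm,
                                min_group = min_group,
                                seed = derive_seed(seed, 202L))
        out$direction <- dir
        out
      }))
    }
  }

  # --- expression concordance for significant regions ----------------------
  if ("expression" %in% stages && !is.null(cohort$expr_counts)) {
    sig <- list()
    if (!is.null(report$fisher)) {
      f <- report$fisher[report$fisher$flagged, c("chrom", "start", "end", "direction")]
      sig[[length(sig) + 1]] <- f
    }
    if (!is.null(report$survival)) {
      s <- report$survival[report$survival$significant,
                           c("chrom", "start", "end", "direction")]
      sig[[length(sig) + 1]] <- s
    }
    sig <- unique(do.call(rbind, sig))
    if (!is.null(sig) && nrow(sig) > 0) {
      ev_by_dir <- list(gain = em$gain, loss = em$loss)
      conc <- lapply(seq_len(nrow(sig)), function(i) {
        reg <- sig[i, ]
        ev <- ev_by_dir[[reg$direction]]
        ridx <- which(em$regions$chrom == reg$chrom &
                      em$regions$start >= reg$start & em$regions$end <= reg$end)
        carrier <- colSums(ev[ridx, , drop = FALSE]) > 0
        res <- expression_concordance(cohort$expr_counts, cohort$genes, reg,
                                      carrier, reg$direction)
        if (nrow(res) == 0) return(NULL)
        cbind(reg[rep(1, nrow(res)), ], res, row.names = NULL)
      })
      conc <- Filter(Negate(is.null), conc)
      if (length(conc)) report$concordance <- do.call(rbind, conc)
    }
  }

  cfg <- list(seed = seed, segmentation = segmentation,
              thresholds = as.list(thresholds), recurrence_B = recurrence_B,
              scan_B = scan_B, fisher_p_flag = fisher_p_flag,
              alpha_perm = alpha_perm, min_group = min_group, stages = stages)
  report$provenance <- list(
    seed = seed, config_hash = config_hash(cfg),
    n_samples = length(samples),
    stage_rows = vapply(report[vapply(report, is.data.frame, TRUE)], nrow, 0L))
  structure(report, class = "cna_report")
}

#' @export
print.cna_report <- function(x, ...) {
  cat("CNA analysis report\n")
  cat(sprintf("  samples: %d; seed: %d; config: %s\n",
              x$provenance$n_samples, x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  for (nm in names(x$provenance$stage_rows))
    cat(sprintf("  %-12s %d rows\n", nm, x$provenance$stage_rows[[nm]]))
  invisible(x)
}

#' Overlap two genomic interval sets
#'
#' Reports pairs of intervals from `set_A` and `set_B` overlapping by at
#' least `min_overlap_bp`, plus the count of A-intervals with at least one
#' partner — the cross-cohort region-validation operation.
#'
#' @param set_A,set_B `data.frame`s with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return List: `pairs` (`data.frame` of indices `a`, `b` and
#'   `overlap_bp`), `n_A_matched`, `n_A`, `fraction_A_matched`.
#' @export
#' @examples
#' a <- data.frame(chrom = "chr1", start = 100, end = 200)
#' b <- data.frame(chrom = "chr1", start = 150, end = 300)
#' intersect_regions(a, b)$pairs$overlap_bp   # 50
intersect_regions <- function(set_A, set_B, min_overlap_bp = 1) {
  validate_intervals(set_A, "set_A")
  validate_intervals(set_B, "set_B")
  gr_A <- GenomicRanges::GRanges(set_A$chrom,
                                 IRanges::IRanges(set_A$start + 1, set_A$end))
  gr_B <- GenomicRanges::GRanges(set_B$chrom,
                                 IRanges::IRanges(set_B$start + 1, set_B$end))
  # disjoint chromosome sets are a legitimate zero-overlap case
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_A, gr_B,
                                minoverlap = as.integer(min_overlap_bp)))
  a <- S4Vectors::queryHits(hits)
  b <- S4Vectors::subjectHits(hits)
  ov <- pmin(set_A$end[a], set_B$end[b]) - pmax(set_A$start[a], set_B$start[b])
  pairs <- data.frame(a = a, b = b, overlap_bp = ov)
  list(pairs = pairs, n_A_matched = length(unique(a)), n_A = nrow(set_A),
       fraction_A_matched = length(unique(a)) / nrow(set_A))
}
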