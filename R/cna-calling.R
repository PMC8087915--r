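#' Compute the per-target log2 tumor/normal coverage ratio
#'
#' Matched ("pseudo-CGH") processing of exome coverage: tumor and normal
#' per-target read counts are scaled to equal totals, a pseudocount guards
#' zero counts, and the resulting `log2((t + c) / (n + c))` track is
#' median-centered. Global ploidy is unidentifiable from coverage ratios, so
#' a uniform doubling of tumor counts yields an all-zero track.
#'
#' Sex-chromosome targets are dropped at ingestion; all downstream analyses
#' are autosomal.
#'
#' @param tumor_counts,normal_counts Non-negative integer vectors on the
#'   same target map (`normal_counts` may also be a pooled reference from
#'   [build_pooled_reference()]).
#' @param targets `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `target_id`, aligned with the count vectors.
#' @param pseudocount Added to both scaled counts (default 1).
#' @param sample_id Sample label stored in the track.
#' @param reference_kind `"matched"` or `"pooled"`.
#' @return A `data.frame` of class `"ratio_track"` with the target columns
#'   and `log2_ratio`; attributes `sample_id` and `reference_kind`.
#' @export
#' @examples
#' tg <- data.frame(chrom = "chr1", start = 0:3 * 100, end = 1:4 * 100)
#' compute_log2_ratio(c(100, 100, 200, 100), rep(100, 4), tg)$log2_ratio
compute_log2_ratio <- function(tumor_counts, normal_counts, targets,
                               pseudocount = 1, sample_id = "sample",
                               reference_kind = c("matched", "pooled")) {
  reference_kind <- match.arg(reference_kind)
  validate_intervals(targets, "targets")
  assert_that(length(tumor_counts) == nrow(targets) &&
              length(normal_counts) == nrow(targets),
              "count vectors and target map differ in length")
  assert_that(all(tumor_counts >= 0) && all(normal_counts >= 0),
              "counts must be non-negative")
  keep <- !is_sex_chrom(targets$chrom)
  targets <- targets[keep, , drop = FALSE]
  t_i <- as.numeric(tumor_counts[keep])
  n_i <- as.numeric(normal_counts[keep])
  assert_that(sum(n_i) > 0, "all-zero normal profile")
  assert_that(sum(t_i) > 0, "all-zero tumor profile")
  # scale both profiles to equal totals
  t_i <- t_i * sum(n_i) / sum(t_i)
  r <- log2((t_i + pseudocount) / (n_i + pseudocount))
  assert_that(all(is.finite(r)), "non-finite log2 ratios")
  r <- r - median(r)
  out <- targets
  if (is.null(out$target_id))
    out$target_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out$log2_ratio <- r
  structure(out, class = c("ratio_track", "data.frame"),
            sample_id = sample_id, reference_kind = reference_kind)
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("Log2 ratio track '%s' (%s reference): %d targets, %d chromosome(s)\n",
              attr(x, "sample_id"), attr(x, "reference_kind"),
              nrow(x), length(unique(x$chrom))))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Build a pooled normal reference profile
#'
#' For samples without a matched normal, a synthetic reference is built from
#' the remaining patients' normals: each normal profile is scaled to the
#' common mean total, then averaged per target.
#'
#' @param normal_counts Matrix (targets x samples) or list of count vectors;
#'   at least 2 normals on the same target map.
#' @return Numeric vector of per-target reference coverage.
#' @export
build_pooled_reference <- function(normal_counts) {
  if (is.list(normal_counts) && !is.data.frame(normal_counts))
    normal_counts <- do.call(cbind, normal_counts)
  normal_counts <- as.matrix(normal_counts)
  assert_that(ncol(normal_counts) >= 2, "need at least 2 normal profiles")
  totals <- colSums(normal_counts)
  assert_that(all(totals > 0), "all-zero normal profile")
  scaled <- sweep(normal_counts, 2, mean(totals) / totals, `*`)
  rowMeans(scaled)
}

# Best single split of x at cut k (left = 1..k): two-sample t statistic with
# pooled variance, computed for all admissible cuts via cumulative sums.
split_t_stats <- function(x, min_targets) {
  L <- length(x)
  k <- seq_len(L - 1)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  nl <- k; nr <- L - k
  ml <- cs[k] / nl
  mr <- (cs[L] - cs[k]) / nr
  ssl <- cs2[k] - nl * ml^2
  ssr <- (cs2[L] - cs2[k]) - nr * mr^2
  s2 <- (ssl + ssr) / pmax(L - 2, 1)
  tt <- abs(ml - mr) / sqrt(pmax(s2, 0) * (1 / nl + 1 / nr))
  tt[is.nan(tt)] <- 0            # zero pooled variance, equal means
  tt[!is.finite(tt)] <- Inf      # zero pooled variance, unequal means
  tt[k < min_targets | (L - k) < min_targets] <- -Inf
  tt
}

# Recursive change-point search on one chromosome; returns sorted cut indices.
segment_chrom <- function(x, alpha_split, n_perm, min_targets) {
  L <- length(x)
  if (L < 2 * min_targets) return(integer(0))
  tt <- split_t_stats(x, min_targets)
  best <- which.max(tt)
  t_obs <- tt[best]
  if (!is.finite(t_obs) && t_obs < 0) return(integer(0))
  if (is.infinite(t_obs)) {
    p <- 0     # exact level change with zero within-segment variance
  } else {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      tp <- split_t_stats(sample(x), min_targets)
      if (max(tp) >= t_obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  if (p >= alpha_split) return(integer(0))
  left <- segment_chrom(x[seq_len(best)], alpha_split, n_perm, min_targets)
  right <- segment_chrom(x[(best + 1):L], alpha_split, n_perm, min_targets)
  sort(c(left, best, best + right))
}

#' Segment a log2 ratio track into piecewise-constant copy-number segments
#'
#' Recursive binary change-point search per chromosome: each candidate split
#' maximizes the two-sample t statistic over cut positions and is kept when
#' its within-segment permutation p-value falls below `alpha_split`; the
#' search recurses into both halves. Adjacent segments whose means differ by
#' less than `merge_delta` are then merged. Segments always tile the target
#' map of each chromosome.
#'
#' @param track A [`ratio_track`][compute_log2_ratio()].
#' @param alpha_split Significance level for keeping a split (default 0.01).
#' @param n_perm Permutations per split test (default 200).
#' @param min_targets Minimum targets per segment (default 3).
#' @param merge_delta Merge adjacent segments with `|mean difference|` below
#'   this value (default 0.1).
#' @param seed Integer seed for the split permutations, so segmentation is
#'   reproducible run to run.
#' @return `data.frame` of class `"sample_segmentation"`: `chrom`, `start`,
#'   `end`, `n_targets`, `mean_log2` (plus target index bounds); attribute
#'   `sample_id`.
#' @export
segment_ratios <- function(track, alpha_split = 0.01, n_perm = 200,
                           min_targets = 3, merge_delta = 0.1, seed = 1L) {
  assert_that(all(is.finite(track$log2_ratio)), "track has non-finite values")
  set.seed(as.integer(seed))
  segs <- list()
  for (chrom in unique(track$chrom)) {
    idx <- which(track$chrom == chrom)
    x <- track$log2_ratio[idx]
    cuts <- segment_chrom(x, alpha_split, n_perm, min_targets)
    bounds <- c(0, cuts, length(x))
    for (s in seq_len(length(bounds) - 1)) {
      i0 <- bounds[s] + 1; i1 <- bounds[s + 1]
      segs[[length(segs) + 1]] <- data.frame(
        chrom = chrom,
        start = track$start[idx[i0]], end = track$end[idx[i1]],
        first_target = idx[i0], last_target = idx[i1],
        n_targets = i1 - i0 + 1,
        mean_log2 = mean(x[i0:i1]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  out <- merge_segments(out, merge_delta)
  structure(out, class = c("sample_segmentation", "data.frame"),
            sample_id = attr(track, "sample_id"))
}

# Iteratively merge the adjacent same-chromosome pair with the smallest mean
# gap until all gaps >= merge_delta.
merge_segments <- function(segs, merge_delta) {
  repeat {
    if (nrow(segs) < 2) break
    gap <- abs(diff(segs$mean_log2))
    gap[segs$chrom[-1] != segs$chrom[-nrow(segs)]] <- Inf
    j <- which.min(gap)
    if (gap[j] >= merge_delta) break
    w1 <- segs$n_targets[j]; w2 <- segs$n_targets[j + 1]
    segs$end[j] <- segs$end[j + 1]
    segs$last_target[j] <- segs$last_target[j + 1]
    segs$mean_log2[j] <- (w1 * segs$mean_log2[j] + w2 * segs$mean_log2[j + 1]) /
      (w1 + w2)
    segs$n_targets[j] <- w1 + w2
    segs <- segs[-(j + 1), , drop = FALSE]
  }
  rownames(segs) <- NULL
  segs
}

#' @export
print.sample_segmentation <- function(x, ...) {
  cat(sprintf("Segmentation '%s': %d segments over %d chromosome(s)\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$chrom))))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Assign five-level copy-number calls to segments
#'
#' Thresholds on the segment mean log2 ratio, all inclusive on the aberrant
#' side: `>= high_gain` is high-gain, `>= gain` gain, `<= hom_loss`
#' homozygous loss, `<= loss` loss, anything between `loss` and `gain`
#' neutral.
#'
#' @param segmentation A [`sample_segmentation`][segment_ratios()].
#' @param thresholds Named numeric vector with `hom_loss < loss < 0 < gain <
#'   high_gain`; defaults `c(hom_loss = -1, loss = -0.2, gain = 0.2,
#'   high_gain = 1)`.
#' @return The segmentation with an added `call` factor column.
#' @export
call_segments <- function(segmentation,
                          thresholds = c(hom_loss = -1, loss = -0.2,
                                         gain = 0.2, high_gain = 1)) {
  th <- thresholds
  assert_that(all(c("hom_loss", "loss", "gain", "high_gain") %in% names(th)),
              "thresholds must name hom_loss, loss, gain, high_gain")
  assert_that(th["hom_loss"] < th["loss"] && th["loss"] < 0 &&
              0 < th["gain"] && th["gain"] < th["high_gain"],
              "thresholds must be ordered hom_loss < loss < 0 < gain < high_gain")
  m <- segmentation$mean_log2
  call <- rep("neutral", length(m))
  call[m >= th["gain"]] <- "gain"
  call[m >= th["high_gain"]] <- "high_gain"
  call[m <= th["loss"]] <- "loss"
  call[m <= th["hom_loss"]] <- "homozygous_loss"
  segmentation$call <- factor(call, levels = c("homozygous_loss", "loss",
                                               "neutral", "gain", "high_gain"))
  segmentation
}

#' Per-sample quality metrics for a copy-number profile
#'
#' The noise metric is the derivative log-ratio spread (DLRS): the median
#' absolute difference of adjacent same-chromosome log2 ratios divided by
#' `sqrt(2)`, a robust estimate of the per-target standard deviation that is
#' insensitive to true copy-number steps. Chromosomes with a single target
#' contribute no adjacent pairs.
#'
#' @param track A [`ratio_track`][compute_log2_ratio()].
#' @param segmentation Optional called segmentation (from [call_segments()]);
#'   enables `n_segments` and `fraction_genome_altered` (non-neutral bp over
#'   total bp).
#' @return List of class `"qc_report"`: `sample_id`, `dlrs`, `n_segments`,
#'   `fraction_genome_altered`.
#' @export
qc_metrics <- function(track, segmentation = NULL) {
  assert_that(nrow(track) > 0, "empty track")
  diffs <- unlist(lapply(split(track$log2_ratio, track$chrom), function(x) {
    if (length(x) < 2) numeric(0) else abs(diff(x))
  }), use.names = FALSE)
  dlrs <- if (length(diffs)) median(diffs) / sqrt(2) else NA_real_
  n_segments <- NA_integer_
  fga <- NA_real_
  if (!is.null(segmentation)) {
    n_segments <- nrow(segmentation)
    if (!is.null(segmentation$call)) {
      bp <- segmentation$end - segmentation$start
      fga <- sum(bp[segmentation$call != "neutral"]) / sum(bp)
    }
  }
  structure(list(sample_id = attr(track, "sample_id"), dlrs = dlrs,
                 n_segments = n_segments, fraction_genome_altered = fga),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC '%s': DLRS = %.4f, %s segments, FGA = %s\n",
              x$sample_id, x$dlrs,
              ifelse(is.na(x$n_segments), "?", x$n_segments),
              ifelse(is.na(x$fraction_genome_altered), "?",
                     sprintf("%.3f", x$fraction_genome_altered))))
  invisible(x)
}
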