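#' GISTIC-style G-score of recurrent aberration
#'
#' Per region, the G-score aggregates frequency and amplitude:
#' `G_r = (1/N) * sum_s amplitude[r, s] * event[r, s]`, with the amplitude
#' capped (default 2.0) so extreme focal amplifications do not dominate.
#' Gains and losses are scored in separate passes.
#'
#' @param matrix An [`event_matrix`][event_matrix()].
#' @param direction `"gain"` or `"loss"`.
#' @param cap Amplitude cap (default 2).
#' @return Numeric vector of per-region G-scores.
#' @export
gscore <- function(matrix, direction = c("gain", "loss"), cap = 2) {
  direction <- match.arg(direction)
  ev <- direction_events(matrix, direction)
  assert_that(ncol(ev) >= 1, "empty event matrix")
  rowMeans(ev * pmin(matrix$amplitude, cap))
}

#' Permutation significance of recurrent aberration (Q-bound)
#'
#' Builds the chance null by independently cyclic-shifting each sample's
#' event-amplitude track across the region grid: per-sample event burden
#' and segment autocorrelation are preserved, only genomic position is
#' randomized. The empirical per-region p-value is
#' `(1 + #\{null G >= observed G\}) / (B + 1)`, adjusted by
#' Benjamini-Hochberg into the Q-bound; regions with `q <= 0.05` are deemed
#' significantly recurrent.
#'
#' @inheritParams gscore
#' @param B Number of permutations (`>= 99`); with fewer than `1/0.05 - 1`
#'   permutations the reporting threshold is unreachable and a warning is
#'   issued.
#' @param seed Integer seed.
#' @param q_max Significance threshold on the Q-bound (default 0.05).
#' @return `data.frame` of class `"recurrence_scores"`: region columns,
#'   `direction`, `freq`, `G`, `p`, `q`, `significant`.
#' @export
recurrence_significance <- function(matrix, direction = c("gain", "loss"),
                                    B = 999, seed = 1L, cap = 2, q_max = 0.05) {
  direction <- match.arg(direction)
  assert_that(B >= 99, "B must be at least 99")
  if (1 / (B + 1) > q_max)
    warning("minimum attainable p exceeds the significance threshold")
  ev <- direction_events(matrix, direction)
  amp <- pmin(matrix$amplitude, cap) * ev
  nr <- nrow(amp); ns <- ncol(amp)
  assert_that(nr >= 1 && ns >= 1, "empty event matrix")
  g_obs <- rowMeans(amp)
  set.seed(as.integer(seed))
  exceed <- integer(nr)
  shifted <- amp
  for (b in seq_len(B)) {
    offs <- sample.int(nr, ns, replace = TRUE) - 1L
    for (j in seq_len(ns)) {
      o <- offs[j]
      if (o > 0) {
        idx <- c((nr - o + 1):nr, seq_len(nr - o))
        shifted[, j] <- amp[idx, j]
      } else shifted[, j] <- amp[, j]
    }
    g_null <- rowMeans(shifted)
    exceed <- exceed + (g_null >= g_obs)
  }
  p <- (1 + exceed) / (B + 1)
  q <- p.adjust(p, method = "BH")
  out <- cbind(matrix$regions,
               data.frame(direction = direction,
                          freq = rowMeans(ev), G = g_obs, p = p, q = q,
                          significant = q <= q_max))
  structure(out, class = c("recurrence_scores", "data.frame"),
            B = B, cap = cap, q_max = q_max)
}

#' Extract significant focal peaks from recurrence scores
#'
#' Maximal runs of contiguous significant regions (adjacent on the grid,
#' same chromosome, touching coordinates) are merged into peaks. Peaks
#' wider than `max_span_bp` are flagged broad and excluded from the focal
#' list. Optionally applies a post-filter keeping only peaks whose maximum
#' G-score is at or below `g_max` — a configurable selection on low
#' G-scores, off by default.
#'
#' @param scores A [`recurrence_scores`][recurrence_significance()].
#' @param max_span_bp Maximum focal peak span in bp (default `Inf`).
#' @param g_max Optional upper G-score bound applied to reported peaks
#'   (`NULL` = no filter).
#' @return `data.frame` of focal peaks: `chrom`, `start`, `end`,
#'   `n_regions`, `max_G`, `min_q`, `broad`.
#' @export
extract_focal_peaks <- function(scores, max_span_bp = Inf, g_max = NULL) {
  sig <- which(scores$significant)
  if (!length(sig)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_regions = integer(0),
                      max_G = numeric(0), min_q = numeric(0),
                      broad = logical(0)))
  }
  # contiguity: consecutive rows, same chromosome, abutting intervals
  brk <- c(TRUE, diff(sig) != 1 |
             scores$chrom[sig[-1]] != scores$chrom[sig[-length(sig)]] |
             scores$start[sig[-1]] != scores$end[sig[-length(sig)]])
  run <- cumsum(brk)
  peaks <- do.call(rbind, lapply(split(sig, run), function(ii) {
    data.frame(chrom = scores$chrom[ii[1]],
               start = scores$start[ii[1]],
               end = scores$end[ii[length(ii)]],
               n_regions = length(ii),
               max_G = max(scores$G[ii]),
               min_q = min(scores$q[ii]),
               stringsAsFactors = FALSE)
  }))
  rownames(peaks) <- NULL
  peaks$broad <- (peaks$end - peaks$start) > max_span_bp
  out <- peaks[!peaks$broad, , drop = FALSE]
  if (!is.null(g_max)) out <- out[out$max_G <= g_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}
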