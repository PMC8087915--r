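#' Construct a regions x samples event matrix from called segmentations
#'
#' The region grid is the union breakpoint grid of all samples' segments:
#' within each chromosome, every distinct segment boundary becomes a grid
#' edge, so each grid region lies inside exactly one segment of every
#' sample. Per (region, sample) the matrix records a gain event (call gain
#' or high-gain), a loss event (loss or homozygous loss), and the amplitude
#' `|mean_log2|` of the covering segment (0 when there is no event).
#'
#' @param segmentations Named list of called segmentations (one per sample,
#'   from [call_segments()]).
#' @return List of class `"event_matrix"`: `regions` (`data.frame` with
#'   `chrom`, `start`, `end`), `samples`, and regions x samples matrices
#'   `gain`, `loss`, `amplitude`.
#' @export
build_event_matrix <- function(segmentations) {
  assert_that(length(segmentations) >= 1, "need at least one segmentation")
  ids <- names(segmentations)
  if (is.null(ids))
    ids <- vapply(segmentations, function(s) attr(s, "sample_id") %||% "", "")
  assert_that(all(nzchar(ids)), "segmentations must be named by sample")
  all_segs <- do.call(rbind, lapply(seq_along(segmentations), function(i) {
    s <- as.data.frame(segmentations[[i]])
    assert_that(!is.null(s$call), "segmentations must carry calls")
    s$sample_id <- ids[i]
    s[, c("sample_id", "chrom", "start", "end", "mean_log2", "call")]
  }))
  regions <- do.call(rbind, lapply(split(all_segs, all_segs$chrom), function(ss) {
    edges <- sort(unique(c(ss$start, ss$end)))
    data.frame(chrom = ss$chrom[1], start = edges[-length(edges)],
               end = edges[-1], stringsAsFactors = FALSE)
  }))
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  nr <- nrow(regions)
  ns <- length(ids)
  gain <- loss <- amp <- matrix(0, nrow = nr, ncol = ns,
                                dimnames = list(NULL, ids))
  for (j in seq_len(ns)) {
    s <- as.data.frame(segmentations[[j]])
    for (k in seq_len(nrow(s))) {
      hit <- regions$chrom == s$chrom[k] &
        regions$start >= s$start[k] & regions$end <= s$end[k]
      cl <- as.character(s$call[k])
      if (cl %in% c("gain", "high_gain")) {
        gain[hit, j] <- 1
        amp[hit, j] <- abs(s$mean_log2[k])
      } else if (cl %in% c("loss", "homozygous_loss")) {
        loss[hit, j] <- 1
        amp[hit, j] <- abs(s$mean_log2[k])
      }
    }
  }
  event_matrix(regions, gain, loss, amp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble an event matrix from its components
#'
#' Lower-level constructor used by [build_event_matrix()], by the simulation
#' helpers, and by file readers.
#'
#' @param regions Sorted, non-overlapping `data.frame` with `chrom`,
#'   `start`, `end`.
#' @param gain,loss 0/1 matrices (regions x samples).
#' @param amplitude Non-negative matrix of `|mean_log2|` values (0 where no
#'   event); defaults to the event indicator itself.
#' @return An object of class `"event_matrix"`.
#' @export
event_matrix <- function(regions, gain, loss, amplitude = NULL) {
  validate_intervals(regions, "regions")
  gain <- as.matrix(gain); loss <- as.matrix(loss)
  if (is.null(amplitude)) amplitude <- pmax(gain, loss)
  amplitude <- as.matrix(amplitude)
  assert_that(nrow(gain) == nrow(regions) && nrow(loss) == nrow(regions) &&
              nrow(amplitude) == nrow(regions),
              "matrix rows must match regions")
  assert_that(all(gain %in% c(0, 1)) && all(loss %in% c(0, 1)),
              "gain/loss must be 0/1")
  assert_that(all(amplitude >= 0), "amplitudes must be >= 0")
  samples <- colnames(gain) %||% sprintf("S%03d", seq_len(ncol(gain)))
  structure(list(regions = regions, samples = samples,
                 gain = gain, loss = loss, amplitude = amplitude),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("Event matrix: %d regions x %d samples (%d gain, %d loss events)\n",
              nrow(x$regions), length(x$samples), sum(x$gain), sum(x$loss)))
  invisible(x)
}

# regions x samples event indicator for one direction
direction_events <- function(matrix, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (direction == "gain") matrix$gain else matrix$loss
}
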