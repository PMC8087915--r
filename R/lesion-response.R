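#' Classify lesion-level objective response from a diameter series
#'
#' Applies lesion-level response rules (RECIST 1.0 style, evaluated per
#' lesion on its longest diameter) to an ordered series of measurements:
#'
#' 1. **IRES** (intrinsic resistance) — the diameter at the first evaluation
#'    at or before `eval_week` has increased by >= 20% over baseline;
#' 2. **ARES** (acquired resistance) — a PR or SD phase followed by a
#'    measurement >= 20% above the smallest diameter observed so far
#'    (the running nadir);
#' 3. **PR** (partial response) — the minimum diameter is >= 30% below
#'    baseline, with no subsequent regrowth as in 2;
#' 4. **SD** (stable disease) — neither shrinkage >= 30% from baseline nor
#'    growth >= 20% over the nadir.
#'
#' Growth/shrinkage thresholds are inclusive (`>=`); the SD bounds are the
#' complementary strict inequalities. All rules are ratio-based, so the
#' classification is invariant to rescaling all diameters.
#'
#' @param series `data.frame` with numeric columns `week` (strictly
#'   increasing, starting at 0 = baseline) and `diameter_mm` (`> 0`).
#' @param eval_week Week of the first response evaluation (default 8); the
#'   IRES rule is checked only against the first measurement at or before
#'   this week.
#' @return A list of class `"response_call"` with `class` (one of
#'   `"IRES"`, `"PR"`, `"SD"`, `"ARES"`), `decisive_week`, and `nadir_mm`
#'   (minimum diameter up to the decisive point).
#' @export
#' @examples
#' s <- data.frame(week = c(0, 8, 16), diameter_mm = c(50, 40, 50))
#' classify_lesion(s)$class   # SD phase then 50 >= 1.2 * 40 -> "ARES"
classify_lesion <- function(series, eval_week = 8) {
  assert_that(is.data.frame(series) &&
              all(c("week", "diameter_mm") %in% names(series)),
              "series must have columns week and diameter_mm")
  series <- series[order(series$week), , drop = FALSE]
  wk <- series$week
  d <- series$diameter_mm
  assert_that(length(wk) >= 2, "need at least baseline and one follow-up")
  assert_that(wk[1] == 0, "missing baseline (week 0) measurement")
  assert_that(all(diff(wk) > 0), "weeks must be strictly increasing")
  assert_that(all(d > 0), "diameters must be positive")
  baseline <- d[1]

  # (1) intrinsic resistance at the first scheduled evaluation
  first_eval <- which(wk > 0 & wk <= eval_week)[1]
  if (!is.na(first_eval) && d[first_eval] >= 1.2 * baseline) {
    return(structure(list(class = "IRES", decisive_week = wk[first_eval],
                          nadir_mm = min(d[seq_len(first_eval)])),
                     class = "response_call"))
  }

  # (2) regrowth >= 20% over the running nadir => acquired resistance
  for (i in 2:length(d)) {
    nadir <- min(d[seq_len(i - 1)])
    if (d[i] >= 1.2 * nadir) {
      return(structure(list(class = "ARES", decisive_week = wk[i],
                            nadir_mm = nadir),
                       class = "response_call"))
    }
  }

  # (3) best response from the full series
  nadir <- min(d)
  if (nadir <= 0.7 * baseline) {
    cls <- "PR"
    decisive <- wk[which(d <= 0.7 * baseline)[1]]
  } else {
    cls <- "SD"
    decisive <- wk[length(wk)]
  }
  structure(list(class = cls, decisive_week = decisive, nadir_mm = nadir),
            class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("Lesion response: %s (decisive week %g, nadir %.1f mm)\n",
              x$class, x$decisive_week, x$nadir_mm))
  invisible(x)
}
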