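# Matrix-form log-rank machinery. For survival data (time, event) with k
# distinct event times, precompute the k x n death and at-risk indicator
# matrices; for any carrier matrix C (n x R) the per-region two-group
# log-rank chi-square statistics are then a pair of matrix products, which
# makes the genome-wide permutation scan a BLAS loop.
logrank_precompute <- function(time, event) {
  assert_that(all(time > 0), "survival times must be positive")
  assert_that(sum(event) >= 1, "no events anywhere")
  et <- sort(unique(time[event == 1]))
  D <- outer(et, time, function(t, ti) as.numeric(ti == t)) *
    rep(event, each = length(et))
  R <- outer(et, time, function(t, ti) as.numeric(ti >= t))
  d <- rowSums(D)
  n <- rowSums(R)
  list(D = D, R = R, d = d, n = n)
}

# Per-column chi-square statistics for carrier matrix C (n x R, 0/1).
logrank_stat_matrix <- function(pre, C) {
  d1 <- pre$D %*% C            # k x R: events among carriers at each time
  n1 <- pre$R %*% C            # k x R: carriers at risk
  e1 <- pre$d * n1 / pre$n
  vfac <- ifelse(pre$n > 1,
                 pre$d * (pre$n - pre$d) / (pre$n^2 * (pre$n - 1)), 0)
  v <- colSums(vfac * n1 * (pre$n - n1))
  omE <- colSums(d1 - e1)
  stat <- ifelse(v > 0, omE^2 / v, 0)
  as.numeric(stat)
}

#' Two-group log-rank chi-square statistic
#'
#' Standard `(O - E)^2 / V` form over the pooled distinct event times, with
#' ties handled by the aggregated hypergeometric variance; censored subjects
#' leave the risk set after their time. The statistic is symmetric in the
#' two groups.
#'
#' @param time Positive survival times (e.g. PFS in months).
#' @param event Event indicator (1 = progression observed, 0 = censored).
#' @param group Two-level group membership vector.
#' @return The chi-square-form log-rank statistic (1 df).
#' @export
#' @examples
#' logrank_statistic(c(1, 2, 3, 4), c(0, 0, 1, 1), c("A", "A", "B", "B"))
logrank_statistic <- function(time, event, group) {
  g <- as.factor(group)
  assert_that(nlevels(g) == 2 && all(table(g) > 0),
              "need two non-empty groups")
  pre <- logrank_precompute(time, event)
  C <- base::matrix(as.numeric(g == levels(g)[1]), ncol = 1)
  logrank_stat_matrix(pre, C)
}

#' Genome-wide permutation log-rank scan for survival association
#'
#' For each region, samples carrying the aberration are compared to
#' non-carriers by the log-rank statistic; the p-value is obtained by
#' permuting the (time, event) pairs jointly across samples `B` times and
#' counting permuted statistics at least as large as the observed one:
#' `p = (1 + #\{perm >= obs\}) / (B + 1)`. Joint permutation of time and
#' event preserves the marginal censoring pattern. By default one shared
#' permutation stream drives all regions (making the scan
#' `O(B (n + regions))` at the cost of positively coupled region p-values);
#' `independent_streams = TRUE` permutes each region independently.
#'
#' Regions where carriers or non-carriers number fewer than `min_group`
#' are reported untested (`p = NA`).
#'
#' @param matrix An [`event_matrix`][event_matrix()].
#' @param time,event Survival data aligned with `matrix$samples`.
#' @param direction `"gain"` or `"loss"`.
#' @param B Number of permutations (default 1999, so the 0.005 reporting
#'   threshold is attainable with resolution 5e-4).
#' @param alpha_perm Reporting threshold on the permuted p (default 0.005).
#' @param min_group Minimum carriers and non-carriers per tested region
#'   (default 3).
#' @param seed Integer seed.
#' @param independent_streams Permute each region with its own stream.
#' @return `data.frame`: region columns, `n_carriers`, `observed_stat`,
#'   `p_perm`, `tested`, `significant`.
#' @export
permutation_scan <- function(matrix, time, event,
                             direction = c("gain", "loss"),
                             B = 1999, alpha_perm = 0.005, min_group = 3,
                             seed = 1L, independent_streams = FALSE) {
  direction <- match.arg(direction)
  ev <- direction_events(matrix, direction)
  n <- length(time)
  assert_that(n == ncol(ev) && length(event) == n,
              "survival data must align with the event matrix samples")
  assert_that(B >= 1 / alpha_perm - 1,
              "B too small: the reporting threshold is unreachable")
  C_all <- t(ev)                               # n x R carrier matrix
  n_carriers <- colSums(C_all)
  tested <- n_carriers >= min_group & (n - n_carriers) >= min_group
  out <- cbind(matrix$regions,
               data.frame(n_carriers = as.integer(n_carriers),
                          observed_stat = NA_real_, p_perm = NA_real_,
                          tested = tested))
  if (any(tested)) {
    pre <- logrank_precompute(time, event)
    C <- C_all[, tested, drop = FALSE]
    obs <- logrank_stat_matrix(pre, C)
    set.seed(as.integer(seed))
    exceed <- integer(ncol(C))
    for (b in seq_len(B)) {
      if (independent_streams) {
        Cp <- apply(C, 2, function(col) col[sample.int(n)])
      } else {
        Cp <- C[sample.int(n), , drop = FALSE]
      }
      perm <- logrank_stat_matrix(pre, Cp)
      exceed <- exceed + (perm >= obs)
    }
    out$observed_stat[tested] <- obs
    out$p_perm[tested] <- (1 + exceed) / (B + 1)
  }
  out$significant <- !is.na(out$p_perm) & out$p_perm <= alpha_perm
  attr(out, "B") <- B
  attr(out, "alpha_perm") <- alpha_perm
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and reports the step function with its
#' at-risk table. The median survival is the smallest time at which the
#' estimate drops to 0.5 or below (undefined when never reached).
#'
#' @inheritParams logrank_statistic
#' @return List of class `"km_estimate"`: `steps` (`data.frame` with
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`), `median`, `n`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$steps$surv   # 2/3, 1/3, 0
km_estimate <- function(time, event) {
  assert_that(length(time) >= 1, "empty survival data")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  drop_idx <- which(steps$surv <= 0.5 & steps$n_event > 0)
  med <- if (length(drop_idx)) steps$time[drop_idx[1]] else NA_real_
  structure(list(steps = steps, median = med, n = length(time)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, median = %s\n", x$n,
              ifelse(is.na(x$median), "not reached", format(x$median))))
  print.data.frame(x$steps)
  invisible(x)
}

#' @export
plot.km_estimate <- function(x, xlab = "Time (months)",
                             ylab = "Survival probability", ...) {
  t <- c(0, x$steps$time)
  s <- c(1, x$steps$surv)
  graphics::plot(t, s, type = "s", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
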