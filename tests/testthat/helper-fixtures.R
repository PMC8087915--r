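# Shared fixture builders; everything is generated in code.

# A minimal target map: one or more chromosomes of `n` abutting targets.
toy_targets <- function(n, chroms = "chr1", width = 1000L) {
  do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch, start = (seq_len(n) - 1L) * width,
               end = seq_len(n) * width, stringsAsFactors = FALSE)
  }))
}

# Ratio track straight from a numeric vector (already centered by caller).
toy_track <- function(values, chroms = "chr1", sample_id = "S1") {
  n <- length(values) / length(chroms)
  tg <- toy_targets(n, chroms)
  tg$target_id <- sprintf("t%d", seq_len(nrow(tg)))
  tg$log2_ratio <- values
  structure(tg, class = c("ratio_track", "data.frame"),
            sample_id = sample_id, reference_kind = "matched")
}

# Event matrix on an abutting grid of `n_regions`, from 0/1 matrices.
toy_event_matrix <- function(gain, loss = NULL, amplitude = NULL,
                             width = 1000L) {
  gain <- as.matrix(gain)
  if (is.null(loss)) loss <- gain * 0
  regions <- data.frame(chrom = "chr1",
                        start = (seq_len(nrow(gain)) - 1L) * width,
                        end = seq_len(nrow(gain)) * width)
  event_matrix(regions, gain, loss, amplitude)
}

# Exact two-tailed Fisher p by full hypergeometric enumeration over all
# tables with the observed margins (probability-at-most-observed rule).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Hand step-up BH (p * m / rank, then running min from the largest p down),
# mapped back to the input order.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact permutation p for a one-region log-rank scan at small n: permuting
# (time, event) jointly against a fixed carrier vector is equivalent to
# re-choosing which k samples carry, uniformly over subsets.
logrank_perm_exact <- function(time, event, carrier) {
  k <- sum(carrier)
  n <- length(time)
  subs <- utils::combn(n, k)
  obs <- logrank_statistic(time, event, ifelse(carrier, "c", "n"))
  stats <- apply(subs, 2, function(ii) {
    g <- rep("n", n); g[ii] <- "c"
    logrank_statistic(time, event, g)
  })
  mean(stats >= obs - 1e-12)
}
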