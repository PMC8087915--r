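#' Reads per kilobase per million mapped reads (RPKM)
#'
#' `rpkm = 1e9 * count / (length_bp * library_size)`.
#'
#' @param counts Gene x sample count matrix (or vector).
#' @param gene_lengths Exonic lengths in bp (`> 0`), one per gene.
#' @param library_sizes Per-sample totals (`> 0`); default `colSums(counts)`.
#' @return Matrix (or vector) of RPKM values.
#' @export
#' @examples
#' compute_rpkm(10, 1000, 1e6)   # 10
compute_rpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  assert_that(all(gene_lengths > 0), "gene lengths must be > 0")
  assert_that(all(library_sizes > 0), "library sizes must be > 0")
  assert_that(length(gene_lengths) == nrow(counts),
              "one length per gene required")
  out <- 1e9 * sweep(counts / gene_lengths, 2, library_sizes, `/`)
  if (ncol(out) == 1 && is.null(colnames(out))) drop(out) else out
}

# NB log-likelihood profile MLE of the mean with per-sample size factors and
# fixed dispersion; counts x, factors s (mean 1), returns list(mu, loglik).
nb_fit_mean <- function(x, s, phi) {
  m0 <- max(mean(x / s), 1e-8)
  if (phi <= 1e-12 || all(x == 0)) {
    mu <- m0
  } else {
    ll <- function(lmu) sum(dnbinom(x, size = 1 / phi, mu = exp(lmu) * s, log = TRUE))
    opt <- optimize(ll, lower = log(m0) - 4, upper = log(m0) + 4, maximum = TRUE)
    mu <- exp(opt$maximum)
  }
  list(mu = mu, loglik = sum(dnbinom(x, size = 1 / phi, mu = mu * s, log = TRUE)))
}

#' Negative-binomial test of differential expression between carriers
#' and non-carriers
#'
#' Per gene: counts are normalized by library-size factors, the dispersion
#' is estimated by method-of-moments on the normalized counts pooled across
#' the two groups (floored at 1e-8), and a two-sided p-value comes from a
#' negative-binomial likelihood-ratio test of equal means (chi-square, 1 df).
#' The fold change is the ratio of normalized group means
#' (carriers / non-carriers).
#'
#' @param counts Gene x sample count matrix.
#' @param carrier Logical/0-1 vector over samples: `TRUE` = aberration
#'   carrier.
#' @param library_sizes Per-sample totals (default `colSums(counts)`).
#' @return `data.frame`: `gene_id`, `mean_carrier`, `mean_noncarrier`,
#'   `fc`, `p`, `tested`. Genes are untested (`p = NA`) when either group
#'   has fewer than 2 samples.
#' @export
nb_test <- function(counts, carrier, library_sizes = NULL) {
  counts <- as.matrix(counts)
  carrier <- as.logical(carrier)
  assert_that(length(carrier) == ncol(counts),
              "carrier vector must match samples")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  assert_that(all(library_sizes > 0), "library sizes must be > 0")
  s <- library_sizes / mean(library_sizes)
  nA <- sum(carrier); nB <- sum(!carrier)
  gene_id <- rownames(counts) %||% sprintf("g%d", seq_len(nrow(counts)))
  tested <- nA >= 2 && nB >= 2
  out <- data.frame(gene_id = gene_id, mean_carrier = NA_real_,
                    mean_noncarrier = NA_real_, fc = NA_real_,
                    p = NA_real_, tested = tested)
  if (!tested) return(out)
  sA <- s[carrier]; sB <- s[!carrier]
  for (i in seq_len(nrow(counts))) {
    xA <- counts[i, carrier]; xB <- counts[i, !carrier]
    zA <- xA / sA; zB <- xB / sB
    mA <- mean(zA); mB <- mean(zB)
    # pooled within-group moments dispersion
    vw <- (sum((zA - mA)^2) + sum((zB - mB)^2)) / (nA + nB - 2)
    mbar <- mean(c(zA, zB))
    phi <- if (mbar > 0) max((vw - mbar) / mbar^2, 1e-8) else 1e-8
    out$mean_carrier[i] <- mA
    out$mean_noncarrier[i] <- mB
    out$fc[i] <- if (mB > 0) mA / mB else if (mA > 0) Inf else NaN
    if (mA == 0 && mB == 0) {
      out$p[i] <- 1
      next
    }
    f0 <- nb_fit_mean(c(xA, xB), c(sA, sB), phi)
    fA <- nb_fit_mean(xA, sA, phi)
    fB <- nb_fit_mean(xB, sB, phi)
    lrt <- max(0, 2 * (fA$loglik + fB$loglik - f0$loglik))
    out$p[i] <- pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  out
}

#' Copy-number / expression concordance rule
#'
#' A gene is concordant with the aberration carried over it when the
#' expression floor is passed (mean and median RPKM both above
#' `rpkm_floor`, evaluated in the higher-expressing group — or in both
#' groups with `both_groups = TRUE`), the FDR-adjusted p-value is below
#' `fdr_max`, and the fold change exceeds `fc_min` in the direction of the
#' copy-number event (strictly `fc > fc_min` for gains, `fc < 1/fc_min`
#' for losses).
#'
#' @param fc Carrier / non-carrier fold change (`> 0`).
#' @param fdr BH-adjusted p-value.
#' @param cna_direction `"gain"` or `"loss"`.
#' @param rpkm_carrier,rpkm_noncarrier RPKM vectors for the two groups.
#' @param rpkm_floor Expression floor (default 1 RPKM).
#' @param fc_min Fold-change threshold (default 1.5).
#' @param fdr_max FDR threshold (default 0.1).
#' @param both_groups Require the floor in both groups rather than the
#'   higher-expressing one.
#' @return Logical concordance flag.
#' @export
#' @examples
#' concordance_call(2, 0.05, "gain", c(5, 6, 4), c(2, 3, 2))   # TRUE
concordance_call <- function(fc, fdr, cna_direction = c("gain", "loss"),
                             rpkm_carrier, rpkm_noncarrier,
                             rpkm_floor = 1, fc_min = 1.5, fdr_max = 0.1,
                             both_groups = FALSE) {
  cna_direction <- match.arg(cna_direction)
  if (is.na(fc) || is.na(fdr)) return(FALSE)
  floor_ok <- function(x) mean(x) > rpkm_floor && median(x) > rpkm_floor
  expr_ok <- if (both_groups) {
    floor_ok(rpkm_carrier) && floor_ok(rpkm_noncarrier)
  } else {
    hi <- if (mean(rpkm_carrier) >= mean(rpkm_noncarrier)) rpkm_carrier
          else rpkm_noncarrier
    floor_ok(hi)
  }
  dir_ok <- if (cna_direction == "gain") fc > fc_min else fc < 1 / fc_min
  expr_ok && fdr < fdr_max && dir_ok
}

#' Region-level transcriptional validation of copy-number events
#'
#' For each gene inside `region`, tests aberration carriers against
#' non-carriers with [nb_test()], adjusts all tested genes by
#' Benjamini-Hochberg, and applies [concordance_call()].
#'
#' @param counts Gene x sample expression count matrix.
#' @param genes `data.frame` with `gene_id`, `chrom`, `start`, `end`,
#'   `length` for the rows of `counts`.
#' @param region List/`data.frame` row with `chrom`, `start`, `end`.
#' @param carrier Logical vector over samples (aberration carriers).
#' @param cna_direction `"gain"` or `"loss"`.
#' @param ... Passed to [concordance_call()].
#' @return `data.frame` with per-gene `fc`, `p`, `fdr`, `concordant`.
#' @export
expression_concordance <- function(counts, genes, region, carrier,
                                   cna_direction = c("gain", "loss"), ...) {
  cna_direction <- match.arg(cna_direction)
  assert_that(nrow(genes) == nrow(counts), "genes must describe count rows")
  in_region <- genes$chrom == region$chrom &
    genes$start < region$end & genes$end > region$start
  if (!any(in_region)) {
    return(data.frame(gene_id = character(0), fc = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      concordant = logical(0)))
  }
  carrier <- as.logical(carrier)
  lib <- colSums(counts)
  sub <- counts[in_region, , drop = FALSE]
  res <- nb_test(sub, carrier, library_sizes = lib)
  res$fdr <- NA_real_
  ok <- !is.na(res$p)
  res$fdr[ok] <- p.adjust(res$p[ok], "BH")
  rpkm <- compute_rpkm(sub, genes$length[in_region], lib)
  rpkm <- base::matrix(rpkm, nrow = nrow(sub))
  res$concordant <- vapply(seq_len(nrow(res)), function(i) {
    if (is.na(res$fdr[i])) return(FALSE)
    concordance_call(res$fc[i], res$fdr[i], cna_direction,
                     rpkm[i, carrier], rpkm[i, !carrier], ...)
  }, logical(1))
  res
}
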