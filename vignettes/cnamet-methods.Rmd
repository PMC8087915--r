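---
title: "Methods: copy-number inference, recurrence, and outcome association in cnamet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number inference, recurrence, and outcome association in cnamet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnamet)
```

`cnamet` analyses somatic copy-number aberrations (CNAs) in longitudinal
cohorts of metastatic tumor biopsies: samples taken before first-line
therapy ("pre") and at clinical progression ("post"), with
progression-free survival (PFS), treatment annotations, lesion-level
response, and bulk RNA counts on the same patients. This vignette explains
each model, its assumptions, the tunable parameters, and the design
decisions taken where the methodology was genuinely open.

## 1. Coverage ratios and the matched-normal model

For a tumor/normal pair profiled on the same exome target map, the
per-target copy-number signal is

$$ r_i = \log_2\frac{t_i + c}{n_i + c}, $$

after both count profiles are scaled to equal totals, with pseudocount
$c = 1$ guarding zero counts without noticeably biasing deep targets. The
track is then median-centered. Two consequences are worth stating
explicitly:

* **Global ploidy is unidentifiable.** A uniform doubling of the tumor
  genome rescales every $t_i$ equally and disappears in the total scaling;
  `cnamet` makes no attempt to infer absolute copy number, only relative
  segmental deviations.
* **Median centering assumes a mostly neutral genome.** If more than half
  of the (autosomal) targets are aberrant in one direction, the baseline
  shifts toward the aberration. This is the standard failure mode of all
  ratio-based CNA callers.

Samples without a matched normal are processed against a pooled reference:
each available normal is scaled to the common mean total and averaged per
target. Sex chromosomes are dropped at ingestion — the cohorts mix sexes,
so X/Y coverage ratios against a pooled or opposite-configuration reference
are dominated by sex, not somatic, signal.

## 2. Segmentation

The proprietary segmentation used by commercial copy-number suites is not
reproducible, so `cnamet` uses a published, transparent contract with the
same piecewise-constant-mean behavior: recursive binary splitting. Within
each chromosome the candidate change point maximizes the pooled-variance
two-sample $t$ statistic over all admissible cuts; the split is kept when a
within-segment permutation test of that maximal statistic gives
$p < \alpha_{split}$, and the procedure recurses into both halves.
Adjacent segments closer than `merge_delta` in mean are merged afterwards
(smallest gap first, means recombined by target count).

Defaults, with rationale:

| parameter | default | meaning |
|---|---|---|
| `alpha_split` | 0.01 | split acceptance level; conservative against oversegmentation |
| `n_perm` | 200 | permutations per split test; resolution 1/201 ≈ 0.005 < `alpha_split` |
| `min_targets` | 3 | smallest reportable segment, in targets |
| `merge_delta` | 0.1 | log2 units; below typical one-copy contrasts (0.58) but above noise |
| `seed` | run config | split permutations are reseeded so segmentation is reproducible |

A zero within-segment variance with unequal side means (an exact step) is
accepted without permutation — the statistic is infinite and the split is
certain. Segments always tile the chromosome; re-segmenting a track of
segment means reproduces the breakpoints (tested), which is the practical
idempotence one wants from a piecewise-constant model.

Calls are assigned per segment mean with inclusive thresholds, by default
±0.2 for gain/loss and ±1.0 for high-gain/homozygous loss. The ±0.2 level
sits between heterozygous one-copy contrasts diluted by normal-cell
admixture and the noise floor; both pairs are user-settable and validated
for ordering.

Per-sample noise is summarized by the derivative log-ratio spread,
$\mathrm{DLRS} = \mathrm{median}(|r_{i+1}-r_i|)/\sqrt{2}$ over adjacent
same-chromosome targets — a robust scale estimate insensitive to true copy
steps (for Gaussian noise it sits at $0.6745\,\sigma$). Chromosomes with a
single target contribute no pairs. `fraction_genome_altered` is the
non-neutral fraction of base pairs in the called segmentation.

## 3. Recurrence scoring

Per direction (gains and losses scored in separate passes), region $r$ gets

$$ G_r = \frac{1}{N}\sum_s \mathbb{1}[\text{event}_{rs}]\cdot
   \min(|\bar{\ell}_{rs}|, \text{cap}), $$

on the union breakpoint grid of all samples' segments, where
$\bar{\ell}_{rs}$ is the covering segment mean. The amplitude cap (default
2.0) bounds the influence of extreme focal amplifications, following
GISTIC practice. The null preserves what matters in segmented data — each
sample's event burden and autocorrelation — by independently cyclically
shifting each sample's event-amplitude track across the grid. The
empirical p-value $(1 + \#\{G^{null} \ge G_r\})/(B+1)$ is BH-adjusted into
a Q-bound, significant at $q \le 0.05$. Note the attainability constraint:
with $m$ regions the smallest possible $q$ is $m/(B+1)$, so $B$ must grow
with the grid (the default $B = 999$ suits grids up to ~50 regions at
$q \le 0.05$).

Contiguous significant regions merge into peaks; peaks wider than
`max_span_bp` are labeled broad and excluded from the focal list. A
post-filter keeping only peaks with maximum G-score at or below a bound is
available but **off by default**: selecting *low* G-scores runs against
the intent of a recurrence score, and rather than guess, the package
exposes it as an explicit flag (`g_max`) and takes no position.

## 4. Group comparisons and the power calculus

Region-wise frequency contrasts use:

* the **test of equal proportions** (pooled-variance chi-square,
  continuity-corrected by default) for unmatched groups; degenerate tables
  (no events, identical frequencies) return $p = 1$;
* **McNemar's test** for matched pairs: exact two-sided binomial on the
  discordant counts when $b + c < 25$, else the continuity-corrected
  chi-square;
* a genome-wide **two-tailed Fisher's exact** scan, with two reporting
  tiers: an unadjusted $p \le 0.005$ flag and BH-adjusted values
  alongside. Two-tailed is defined by summing hypergeometric probabilities
  of tables no more likely than the observed one — the common convention;
  alternatives (doubling the one-sided p) exist but are not implemented.

The two-tier reporting is a deliberate response to the power situation.
With ~30,000 focal regions, family-wise control at 5% demands a per-test
level of $0.05/29{,}736 = 1.7\times 10^{-6}$. The package's sample-size
calculus (normal approximation with pooled null and unpooled alternative
variance, Fleiss continuity correction) shows that detecting even a 10%
vs 40% carrier-rate difference at that level with 80% power needs 274
patients in total (260 without the correction) — more than realistic
serial-biopsy cohorts. The continuity-corrected form is the default
because uncorrected normal approximations are anticonservative exactly in
the small-count regime these scans live in; both numbers are reported.

## 5. Survival scan

Carriers vs non-carriers of each region are compared by the log-rank
statistic in its $(O-E)^2/V$ form over pooled distinct event times, ties
handled by the aggregated hypergeometric variance, censored subjects
leaving the risk set after their time. Per-region p-values come from
permutation: the (time, event) **pairs** are permuted jointly across
samples — permuting times alone would break the censoring pattern's
coupling to the follow-up process, so the joint permutation is the
standard choice. $B = 1999$ by default so the $p \le 0.005$ reporting
threshold is attainable with resolution $5\times10^{-4}$; regions with
fewer than `min_group` (default 3) carriers or non-carriers are reported
untested rather than given a meaningless p.

One shared permutation stream drives all regions, which reduces the scan
to two matrix products per permutation ($O(B\,k\,n\,R)$ BLAS work for $k$
event times, $n$ samples, $R$ regions) at the cost of positively coupled
region p-values; `independent_streams = TRUE` gives per-region streams at
identical asymptotic cost and is what the null-calibration tests use.
Kaplan–Meier estimation is delegated to `survival::survfit`, with the
median re-derived from the steps as the smallest time at which the
estimate reaches 0.5 or less.

## 6. Expression concordance

A CNA is transcriptionally validated gene by gene. Counts are normalized
by library-size factors; per gene, dispersion is estimated by
method-of-moments on the normalized counts pooled within groups (floored
at $10^{-8}$, where the likelihood degrades gracefully to Poisson), and
equal group means are tested by a negative-binomial likelihood-ratio test
(chi-square, 1 df), the mean under each hypothesis profiled numerically
with the size factors as offsets. The NB machinery is implemented directly
because this specific test — moments dispersion plus LRT on carrier
status per region — *is* part of the defined analysis procedure; generic
differential-expression pipelines estimate shrunken dispersions and
model formulas that would change the procedure being validated.

A gene is **concordant** when all of: mean RPKM > 1 and median RPKM > 1;
FDR (BH across the genes tested per analysis) < 0.1; fold change beyond
1.5 in the CNA direction (fc > 1.5 for gains, fc < 1/1.5 for losses;
strict inequalities). The expression floor is stated ambiguously in the
field's usual phrasing ("average and median minimal value > 1 RPKM");
`cnamet` reads it literally as *both* mean and median above 1 RPKM,
evaluates it in the higher-expressing group (so a silenced non-carrier
group cannot veto a genuinely expressed gain), and offers
`both_groups = TRUE` for the stricter reading.

A practical caveat surfaced by simulation: fold changes are computed on
library-size-normalized counts, so if a planted (or real) aberration
covers a large fraction of the transcriptome, carriers' library sizes
inflate and dilute the apparent fold change — the familiar composition
bias of total-count normalization. For the focal regions this package
targets the effect is negligible.

## 7. Lesion response classification

Longest-diameter series are classified per lesion with inclusive
thresholds: IRES if the first evaluation at or before week 8 shows ≥ 20%
growth over baseline; otherwise any later measurement ≥ 20% above the
running nadir (the smallest diameter so far, baseline included) is ARES —
this deliberately routes "grew late, never responded" to ARES, since the
intrinsic-resistance definition is anchored to the first evaluation; else
PR if the minimum reaches ≤ 70% of baseline, else SD. Every valid series
gets exactly one class, and all rules are ratios, so the classification is
scale invariant.

## 8. The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's recovery and calibration claims hold.

* **Design**: 97 pre- and 43 post-treatment samples by default, mirroring
  the longitudinal liver-metastasis design the package targets; unmatched
  group comparisons use 76 pre vs 43 post in the tests, matching the
  published unmatched contrast.
* **Coverage**: negative-binomial per-target counts (Poisson as dispersion
  → 0), mean depth 5000 per target — targets stand for the binned windows
  of matched-coverage processing, not individual baits — and dispersion
  7e-4, calibrated so the cohort DLRS averages ≈ 0.042, the QC level
  reported for liver-metastasis WES in this setting. Carriers multiply
  in-region tumor means by $2^{\text{log2\_shift}}$.
* **Survival**: exponential progression times with rate
  $\lambda_0 \prod \text{HR}_{\text{carried}}$, $\lambda_0 = \log 2 / 9.7$
  per month (median PFS 9.7 months), independent exponential censoring at
  0.02/month (≈ 20–25% censoring). Constant hazards are the simplest model
  supporting hazard-ratio recovery tests.
* **Expression**: log-normal gene means (log-mean log(100), sd 1),
  NB counts with dispersion 0.1, ±10% log-normal library-size factors;
  carriers' in-region genes scaled by `expr_dosage`.
* **Truth separation**: carrier labels are returned in a separate element
  and written to separate files, never embedded in analysis inputs.

What it does **not** emulate: tumor purity and subclonality (amplitudes
are clean multiples), GC/mappability waves, batch effects, matched
primary tumors, arm-level aneuploidy mixtures, or raw reads. Passing
recovery tests therefore demonstrate the statistics are implemented
correctly and are powered under clean conditions — not that the caller is
robust to every artifact of real exome data.

## 9. Numerical and degenerate-input choices

* Empirical p-values are always $(1 + \text{exceedances})/(B + 1)$,
  honoring the $1/(B+1)$ lower bound; every permutation routine takes a
  seed and is reproducible.
* Coordinates are 0-based half-open internally; SEG export is 1-based
  inclusive, BED 0-based half-open, converted only at the file boundary.
* Zero-variance log-rank contrasts (all events in ties or a fully
  censored group) return statistic 0 rather than NaN; genes with all-zero
  counts in both groups get $p = 1$ and undefined fold change.
* The seeds derived for per-sample segmentation and per-stage permutations
  are deterministic functions of the run seed, kept below $2^{31}$.

## 10. Problem sizes and limitations

The validation suite runs cohorts of 40–119 samples on 60–120 targets per
chromosome over 1–3 chromosomes, grids of up to 2000 regions for null
calibration, and permutation depths $B$ of 199–10,000 — sizes chosen so
the full suite exercises every claim end to end in well under a minute per
test file on a single core. The same machinery scales linearly in targets
and samples (segmentation) and in $B \cdot k \cdot n \cdot R$ (the scan's
BLAS products) for cohort-scale runs.

Known limitations, beyond the generator's scope above: no arm-level/broad
score separate from focal recurrence and no iterative peak deconvolution
("peel-off"); no tumor-purity correction of amplitudes; the recurrence and
survival scans treat regions marginally (no joint model across regions);
and the NB test uses per-gene moment dispersions, which are noisier than
shrinkage estimators at very small group sizes — the minimum of two
samples per group is a hard floor, not a recommendation.
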