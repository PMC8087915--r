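# Plain-text interchange formats. Internal coordinates are 0-based
# half-open; SEG files are written/read 1-based inclusive and BED files
# 0-based half-open, converted at this boundary.

#' Read / write per-target coverage tables
#'
#' Tab-separated columns `target_id`, `chrom`, `start`, `end`, `count`
#' (coordinates 0-based half-open).
#'
#' @param path File path.
#' @return `read_coverage_tsv`: a `data.frame`.
#' @export
read_coverage_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("target_id", "chrom", "start", "end", "count") %in% names(x)),
              "coverage TSV needs target_id/chrom/start/end/count")
  x
}

#' @rdname read_coverage_tsv
#' @param targets Target map `data.frame` (`chrom`, `start`, `end`,
#'   `target_id`).
#' @param counts Count vector aligned with `targets`.
#' @export
write_coverage_tsv <- function(targets, counts, path) {
  out <- data.frame(target_id = targets$target_id, chrom = targets$chrom,
                    start = targets$start, end = targets$end, count = counts)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write segment tables in SEG format
#'
#' SEG is tab-separated with columns sample, chromosome, start, end,
#' number of markers, and segment mean log2 ratio; coordinates in the file
#' are 1-based inclusive and are converted to the package's 0-based
#' half-open convention on read.
#'
#' @param path File path.
#' @return `read_seg`: a `data.frame` with `sample_id`, `chrom`, `start`,
#'   `end`, `n_targets`, `mean_log2` (0-based half-open).
#' @export
read_seg <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  names(x) <- c("sample_id", "chrom", "start", "end", "n_targets", "mean_log2")
  x$start <- x$start - 1L          # 1-based inclusive -> 0-based half-open
  x
}

#' @rdname read_seg
#' @param segments `data.frame` with `sample_id`, `chrom`, `start`, `end`,
#'   `n_targets`, `mean_log2` (0-based half-open).
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(ID = segments$sample_id, chrom = segments$chrom,
                    loc.start = segments$start + 1L,   # to 1-based inclusive
                    loc.end = segments$end,
                    num.mark = segments$n_targets,
                    seg.mean = round(segments$mean_log2, 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write genomic intervals in BED format
#'
#' BED is 0-based half-open, matching the internal convention; columns
#' beyond chrom/start/end(/name) are ignored on read.
#'
#' @param path File path.
#' @return `read_bed`: `data.frame` with `chrom`, `start`, `end` and
#'   `name` when present.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  validate_intervals(x, "BED intervals")
  x[, intersect(c("chrom", "start", "end", "name"), names(x))]
}

#' @rdname read_bed
#' @param intervals `data.frame` with `chrom`, `start`, `end` and optional
#'   `name`.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  write.table(intervals[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Tab-separated; requires `sample_id` and accepts the standard clinical
#' columns (`patient_id`, `timepoint`, `pfs_months`, `progression`,
#' `bevacizumab`, `regimen`, lesion diameters).
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_clinical_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(nrow(x) > 0, "empty clinical table")
  assert_that("sample_id" %in% names(x), "clinical table needs sample_id")
  x
}

#' Read a gene x sample count matrix with gene annotation
#'
#' Tab-separated with columns `gene_id`, `chrom`, `start`, `end`, `length`
#' followed by one column per sample.
#'
#' @param path File path.
#' @return List with `genes` (`data.frame`) and `counts` (matrix).
#' @export
read_counts_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("gene_id", "chrom", "start", "end", "length")
  assert_that(all(meta %in% names(x)), "counts TSV needs gene annotation columns")
  counts <- as.matrix(x[, setdiff(names(x), meta), drop = FALSE])
  rownames(counts) <- x$gene_id
  list(genes = x[, meta], counts = counts)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Produces per-sample coverage TSVs (tumor and normal), the clinical
#' table, the expression count table, and the ground-truth labels (regions
#' as BED plus carrier labels as JSON) in `dir`. Truth labels live in
#' separate files so they can never leak into analysis inputs.
#'
#' @param cohort A [`cna_cohort`][simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in colnames(cohort$tumor_counts)) {
    write_coverage_tsv(cohort$targets, cohort$tumor_counts[, s],
                       file.path(dir, paste0(s, ".tumor.tsv")))
    write_coverage_tsv(cohort$targets, cohort$normal_counts[, s],
                       file.path(dir, paste0(s, ".normal.tsv")))
  }
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts <- cbind(cohort$genes, as.data.frame(cohort$expr_counts))
  write.table(counts, file.path(dir, "expr_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- cohort$truth$regions
  if (nrow(tr)) {
    tr$name <- rownames(cohort$truth$carriers)
    write_bed(tr, file.path(dir, "truth_regions.bed"))
  }
  jsonlite::write_json(
    list(seed = cohort$seed,
         config_hash = config_hash(unclass(cohort$config)[
           setdiff(names(cohort$config), "truth_regions")]),
         carriers = as.data.frame(cohort$truth$carriers)),
    file.path(dir, "truth_labels.json"))
  invisible(dir)
}
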