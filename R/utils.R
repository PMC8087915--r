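# Internal helpers shared across modules.

SEX_CHROMS <- c("X", "Y", "chrX", "chrY", "23", "24", "chr23", "chr24")

is_sex_chrom <- function(chrom) chrom %in% SEX_CHROMS

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Validate a region/interval data.frame (0-based half-open).
validate_intervals <- function(x, what = "intervals") {
  assert_that(is.data.frame(x) && all(c("chrom", "start", "end") %in% names(x)),
              sprintf("%s must be a data.frame with chrom/start/end", what))
  assert_that(all(x$start < x$end), sprintf("%s: start must be < end", what))
  invisible(x)
}

# Deterministic child seeds derived from one user seed (kept < 2^31).
# Arithmetic in doubles: exact below 2^53, immune to integer overflow.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 1009) %% 2147483647)
}

# Stable short hash of an R object, for provenance records.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
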