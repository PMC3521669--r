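# Shared internal helpers: TSV IO conventions, validation, GRanges bridging.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
check_cols <- function(dt, cols, where) {
  miss <- setdiff(cols, names(dt))
  if (length(miss) > 0L)
    stop(sprintf("%s: missing required column(s): %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(dt)
}

# Package-wide TSV conventions: tab separated, header row, "." for missing.
read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = ".",
                    data.table = TRUE, ...)
}

#' Write a table in the package's TSV dialect
#'
#' Tab-separated, header row, `"."` for missing values.
#'
#' @param dt a data.frame or data.table
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

# 0-based half-open [start, end) -> IRanges (1-based inclusive)
to_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

to_granges <- function(dt, chrom = dt$chrom, start = dt$start, end = dt$end,
                       strand = NULL) {
  if (is.null(strand))
    GenomicRanges::GRanges(seqnames = chrom, ranges = to_iranges(start, end))
  else
    GenomicRanges::GRanges(seqnames = chrom, ranges = to_iranges(start, end),
                           strand = strand)
}

# Point (a single 0-based base position) -> width-1 GRanges
point_granges <- function(chrom, pos0) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos0 + 1L, width = 1L))
}

# Deterministic child seeds below 2^31 derived from a base seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629) + 1L
}

probe_midpoint <- function(start, end) as.integer(floor((start + end) / 2))
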