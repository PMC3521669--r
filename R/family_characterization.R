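# Family attribute summaries by spreading class: superfamily composition,
# rank-sum attribute comparisons, normalized chromosomal distributions and
# small-RNA coverage statistics. Insertion dates and similar attributes are
# externally supplied (attribute table input); no LTR dating is computed.

#' Superfamily composition per spreading class
#'
#' @param classes data.table (family_id, class)
#' @param attributes data.table (family_id, superfamily, ...)
#' @return data.table class, superfamily, n, proportion (proportions per
#'   class sum to 1); unknown superfamily codes are grouped as "other" with
#'   a warning
#' @export
superfamily_composition <- function(classes, attributes) {
  x <- merge(classes, attributes[, .(family_id, superfamily)], by = "family_id")
  bad <- !x$superfamily %in% c(SUPERFAMILIES, "other")
  if (any(bad)) {
    warning(sprintf("superfamily_composition: %d unknown superfamily code(s) grouped as 'other'",
                    sum(bad)))
    x[bad, superfamily := "other"]
  }
  grid <- data.table::CJ(class = unique(x$class),
                         superfamily = c(SUPERFAMILIES, "other"))
  n <- x[, .(n = .N), by = .(class, superfamily)]
  out <- n[grid, on = c("class", "superfamily")]
  out[is.na(n), n := 0L]
  out[, proportion := n / sum(n), by = class]
  out[order(class, superfamily)]
}

#' Compare a family attribute between two spreading classes
#'
#' Two-sided Wilcoxon rank-sum on family-level values (invariant under
#' monotone transforms of the attribute). Missing values are dropped.
#'
#' @param attributes data.table with family_id, class and the attribute
#' @param attribute_name column to compare
#' @param class_a,class_b the two classes
#' @return data.table attribute, class_a, class_b, n_a, n_b, statistic,
#'   p_value
#' @export
compare_attribute <- function(attributes, attribute_name, class_a, class_b) {
  check_cols(attributes, c("family_id", "class", attribute_name),
             "compare_attribute")
  a <- attributes[class == class_a][[attribute_name]]
  b <- attributes[class == class_b][[attribute_name]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("compare_attribute: need >= 2 families with values per class", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  data.table::data.table(attribute = attribute_name, class_a = class_a,
                         class_b = class_b, n_a = length(a), n_b = length(b),
                         statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Normalized chromosomal distribution of copies
#'
#' Copy midpoints are mapped to relative chromosome position in [0, 1) and
#' histogrammed over `n_windows` equal windows; counts are divided by the
#' family's total copy number so each family's distribution sums to 1.
#' Class-level distributions are means of member-family normalized
#' histograms (so large families do not dominate).
#'
#' @param repeats repeat table
#' @param chrom_lengths named chromosome lengths
#' @param n_windows number of windows (default 20)
#' @param classes optional (family_id, class) table; when given, class-level
#'   distributions are returned as well
#' @return list with `family` (family_id, window, abundance) and, when
#'   classes are given, `class` (class, window, abundance)
#' @export
chromosomal_distribution <- function(repeats, chrom_lengths, n_windows = 20L,
                                     classes = NULL) {
  stopifnot(n_windows >= 2)
  if (nrow(repeats) == 0L) stop("chromosomal_distribution: no copies", call. = FALSE)
  rp <- data.table::copy(repeats)
  rp[, rel_pos := pmin(floor((start + end) / 2) / chrom_lengths[chrom], 1 - 1e-9)]
  rp[, window := as.integer(floor(rel_pos * n_windows)) + 1L]
  grid <- data.table::CJ(family_id = unique(rp$family_id), window = 1:n_windows)
  h <- rp[, .(n = .N), by = .(family_id, window)][grid, on = c("family_id", "window")]
  h[is.na(n), n := 0L]
  h[, abundance := n / sum(n), by = family_id]
  fam <- h[, .(family_id, window, abundance)][order(family_id, window)]
  out <- list(family = fam)
  if (!is.null(classes)) {
    hc <- merge(fam, classes, by = "family_id")
    out$class <- hc[, .(abundance = mean(abundance)),
                    by = .(class, window)][order(class, window)]
  }
  out
}

#' Small-RNA coverage statistics per family
#'
#' Per copy: the number of small-RNA intervals overlapping it and the
#' fraction of the copy covered by their union; family values are means over
#' copies.
#'
#' @param smallrna data.table chrom, start, end of mapped small-RNA
#'   intervals
#' @param repeats repeat table
#' @return data.table family_id, mean_read_count_per_copy,
#'   mean_covered_fraction
#' @export
smallrna_stats <- function(smallrna, repeats) {
  rgr <- to_granges(repeats)
  if (nrow(smallrna) == 0L) {
    return(repeats[, .(mean_read_count_per_copy = 0,
                       mean_covered_fraction = 0), by = family_id])
  }
  sgr <- to_granges(smallrna)
  cnt <- GenomicRanges::countOverlaps(rgr, sgr)
  # union coverage: intersect the reduced small-RNA set with each copy
  red <- GenomicRanges::reduce(sgr)
  ov <- GenomicRanges::findOverlaps(rgr, red)
  inter <- IRanges::pintersect(rgr[S4Vectors::queryHits(ov)],
                               red[S4Vectors::subjectHits(ov)])
  covered <- rep(0L, nrow(repeats))
  if (length(inter) > 0L) {
    byc <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(byc))] <- as.integer(byc)
  }
  per_copy <- data.table::data.table(
    family_id = repeats$family_id, count = cnt,
    frac = covered / (repeats$end - repeats$start))
  per_copy[, .(mean_read_count_per_copy = mean(count),
               mean_covered_fraction = mean(frac)), by = family_id][order(family_id)]
}
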