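# Gene expression as a function of distance to the closest upstream TE:
# per-gene RPKM, nearest-upstream-TE proximity records, and
# distance-stratified comparisons between spreading classes.

#' Reads per kilobase of exon model per million mapped reads
#'
#' `10^9 * count / (exon_length_bp * library_size)`.
#'
#' @param count read count(s)
#' @param exon_length_bp summed merged exon length(s) (> 0)
#' @param library_size total mapped reads (> 0)
#' @return numeric RPKM
#' @export
rpkm <- function(count, exon_length_bp, library_size) {
  if (any(exon_length_bp <= 0)) stop("rpkm: exon_length_bp must be > 0", call. = FALSE)
  if (any(library_size <= 0)) stop("rpkm: library_size must be > 0", call. = FALSE)
  1e9 * as.numeric(count) / (as.numeric(exon_length_bp) * as.numeric(library_size))
}

#' Per-gene expression table (RPKM, expressed flag)
#'
#' @param genes gene table (gene_id, exon_length_bp)
#' @param counts counts table (gene_id, sample_id, count)
#' @param libsizes library sizes (sample_id, library_size)
#' @return data.table gene_id, sample_id, count, rpkm, expressed
#'   (expressed iff RPKM > 0)
#' @export
gene_expression <- function(genes, counts, libsizes) {
  x <- libsizes[counts, on = "sample_id"]
  x <- genes[, .(gene_id, exon_length_bp)][x, on = "gene_id"]
  if (anyNA(x$exon_length_bp))
    stop("gene_expression: counts reference unknown gene_id(s)", call. = FALSE)
  x[, rpkm := rpkm(count, exon_length_bp, library_size)]
  x[, expressed := rpkm > 0]
  x[, .(gene_id, sample_id, count, rpkm, expressed)]
}

#' Closest upstream TE for each gene
#'
#' Upstream is gene-strand-relative (5' of the TSS; TSS = start for `+`
#' genes, end for `-` genes). The distance runs from the TSS to the nearest
#' repeat edge on the upstream side; a TSS inside a repeat gets distance 0.
#' The stratum is the smallest cutoff >= distance, else `"none"`.
#'
#' @param genes gene table (gene_id, chrom, start, end, strand)
#' @param repeats repeat table
#' @param cutoffs nested distance cutoffs (default 500/1000/2500/5000)
#' @return data.table gene_id, nearest_family, nearest_copy_id, distance_bp,
#'   stratum
#' @export
nearest_upstream_te <- function(genes, repeats,
                                cutoffs = c(500L, 1000L, 2500L, 5000L)) {
  stopifnot(all(genes$strand %in% c("+", "-")))
  out <- data.table::data.table(gene_id = genes$gene_id,
                                nearest_family = NA_character_,
                                nearest_copy_id = NA_character_,
                                distance_bp = NA_integer_)
  for (cn in unique(genes$chrom)) {
    rp <- repeats[chrom == cn]
    gi <- which(genes$chrom == cn)
    if (nrow(rp) == 0L || length(gi) == 0L) next
    data.table::setorder(rp, start, copy_id)
    for (i in gi) {
      plus <- genes$strand[i] == "+"
      tss <- if (plus) genes$start[i] else genes$end[i]
      # TSS base: for + strand the base at `tss`; for - strand the base at
      # tss - 1. Inside any repeat -> distance 0.
      tssb <- if (plus) tss else tss - 1L
      inside <- which(rp$start <= tssb & rp$end > tssb)
      if (length(inside) > 0L) {
        j <- inside[1]; d <- 0L
      } else if (plus) {
        cand <- which(rp$end <= tss)
        if (length(cand) == 0L) next
        j <- cand[which.max(rp$end[cand])]
        d <- tss - rp$end[j]
      } else {
        cand <- which(rp$start >= tss)
        if (length(cand) == 0L) next
        j <- cand[which.min(rp$start[cand])]
        d <- rp$start[j] - tss
      }
      out$nearest_family[i] <- rp$family_id[j]
      out$nearest_copy_id[i] <- rp$copy_id[j]
      out$distance_bp[i] <- as.integer(d)
    }
  }
  cuts <- sort(cutoffs)
  out[, stratum := ifelse(is.na(distance_bp), "none", NA_character_)]
  for (cc in rev(cuts)) out[!is.na(distance_bp) & distance_bp <= cc,
                            stratum := paste0("<=", cc)]
  out[is.na(stratum), stratum := "none"]
  out[]
}

#' Distance-stratified expression comparison across spreading classes
#'
#' For each cutoff, genes with a nearest upstream TE within the cutoff are
#' grouped by the spreading class of that TE's family and compared
#' (two-sided Wilcoxon rank-sum of RPKM) against (a) the non-spreading
#' class in the same stratum and (b) genes with no TE within the cutoff.
#' Strata are nested by default (`disjoint = TRUE` analyzes
#' (previous, cutoff] bands instead).
#'
#' @param proximity output of [nearest_upstream_te()]
#' @param expression output of [gene_expression()] (one sample)
#' @param classes data.table (family_id, class)
#' @param cutoffs distance cutoffs in bp
#' @param exclude_zeros drop genes with RPKM = 0 before comparing
#' @param disjoint use disjoint distance bands instead of nested cutoffs
#' @return data.table cutoff, class, n_genes, mean_rpkm,
#'   p_vs_nonspreading, p_vs_no_te
#' @export
stratified_comparison <- function(proximity, expression, classes,
                                  cutoffs = c(500L, 1000L, 2500L, 5000L),
                                  exclude_zeros = FALSE, disjoint = FALSE) {
  x <- merge(proximity, expression, by = "gene_id")
  x <- merge(x, classes, by.x = "nearest_family", by.y = "family_id",
             all.x = TRUE)
  if (exclude_zeros) x <- x[rpkm > 0]
  cuts <- sort(cutoffs)
  res <- list()
  for (k in seq_along(cuts)) {
    lo <- if (disjoint && k > 1L) cuts[k - 1L] else -1L
    inb <- x[!is.na(distance_bp) & distance_bp <= cuts[k] & distance_bp > lo]
    none <- x[is.na(distance_bp) | distance_bp > cuts[k]]
    ref <- inb[class == "non_spreading", rpkm]
    for (cl in unique(inb$class[!is.na(inb$class)])) {
      v <- inb[class == cl, rpkm]
      p_ns <- if (cl != "non_spreading" && length(v) >= 2L && length(ref) >= 2L)
        suppressWarnings(stats::wilcox.test(v, ref)$p.value) else NA_real_
      p_no <- if (length(v) >= 2L && nrow(none) >= 2L)
        suppressWarnings(stats::wilcox.test(v, none$rpkm)$p.value) else NA_real_
      res[[length(res) + 1L]] <- data.table::data.table(
        cutoff = cuts[k], class = cl, n_genes = length(v), mean_rpkm = mean(v),
        p_vs_nonspreading = p_ns, p_vs_no_te = p_no)
    }
    res[[length(res) + 1L]] <- data.table::data.table(
      cutoff = cuts[k], class = "no_te", n_genes = nrow(none),
      mean_rpkm = mean(none$rpkm), p_vs_nonspreading = NA_real_,
      p_vs_no_te = NA_real_)
  }
  data.table::rbindlist(res)[order(cutoff, class)]
}

#' Proportion of genes expressed (RPKM > 0) per stratum and class
#'
#' @inheritParams stratified_comparison
#' @return data.table cutoff, class, n_genes, n_expressed, prop_expressed
#' @export
proportion_expressed <- function(proximity, expression, classes,
                                 cutoffs = c(500L, 1000L, 2500L, 5000L),
                                 disjoint = FALSE) {
  x <- merge(proximity, expression, by = "gene_id")
  x <- merge(x, classes, by.x = "nearest_family", by.y = "family_id",
             all.x = TRUE)
  cuts <- sort(cutoffs)
  res <- list()
  for (k in seq_along(cuts)) {
    lo <- if (disjoint && k > 1L) cuts[k - 1L] else -1L
    inb <- x[!is.na(distance_bp) & distance_bp <= cuts[k] & distance_bp > lo]
    none <- x[is.na(distance_bp) | distance_bp > cuts[k]]
    grp <- inb[!is.na(class), .(n_genes = .N, n_expressed = sum(expressed)),
               by = class]
    grp <- rbind(grp, data.table::data.table(class = "no_te",
                                             n_genes = nrow(none),
                                             n_expressed = sum(none$expressed)))
    grp[, `:=`(cutoff = cuts[k],
               prop_expressed = ifelse(n_genes > 0, n_expressed / n_genes, NA_real_))]
    res[[length(res) + 1L]] <- grp
  }
  out <- data.table::rbindlist(res)
  data.table::setcolorder(out, c("cutoff", "class", "n_genes", "n_expressed",
                                 "prop_expressed"))
  out[order(cutoff, class)]
}
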