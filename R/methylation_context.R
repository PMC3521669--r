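# Bisulfite sequence-context methylation summaries: CG/CHG/CHH context
# calling from the genome sequence, percent methylation of low-copy flanks
# and TE interiors, random-region baselines, spreading-group comparisons and
# chromosome-relative positional profiles.

#' Call the methylation context of cytosines from the genome
#'
#' Forward strand: the base at `position` must be C; context is CG if the
#' next base is G, CHG if the base after next is G, else CHH (H = A, C or T).
#' The minus strand is evaluated on the reverse complement (the forward base
#' must be G, read-through runs leftward). Positions closer than 2 bases to
#' the chromosome end on the read-through side return `NA` (context
#' undefined).
#'
#' @param genome `DNAStringSet` (names = chromosome names)
#' @param chrom,position,strand vectors; position is 0-based
#' @return character vector of "CG"/"CHG"/"CHH" (NA where undefined)
#' @export
call_context <- function(genome, chrom, position, strand) {
  stopifnot(length(chrom) == length(position), length(position) == length(strand))
  out <- rep(NA_character_, length(position))
  seqs <- lapply(setNames(names(genome), names(genome)),
                 function(nm) as.character(genome[[nm]]))
  for (cn in unique(chrom)) {
    if (!cn %in% names(seqs)) stop(sprintf("call_context: unknown chromosome '%s'", cn),
                                   call. = FALSE)
    s <- seqs[[cn]]
    L <- nchar(s)
    idx <- which(chrom == cn)
    p <- position[idx]
    if (any(p < 0 | p >= L))
      stop(sprintf("call_context: position out of range on %s", cn), call. = FALSE)
    plus <- strand[idx] == "+"
    # forward strand
    ip <- idx[plus]; pp <- p[plus]
    if (length(ip) > 0L) {
      b0 <- substring(s, pp + 1, pp + 1)
      if (any(b0 != "C"))
        stop(sprintf("call_context: position not a C at %s:%d (+)", cn, pp[b0 != "C"][1]),
             call. = FALSE)
      ok <- pp + 2 <= L - 1          # need two downstream bases
      b1 <- substring(s, pp + 2, pp + 2)
      b2 <- substring(s, pp + 3, pp + 3)
      ctx <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
      out[ip] <- ifelse(ok, ctx, NA_character_)
    }
    # minus strand: forward base must be G; context bases lie at p-1, p-2
    im <- idx[!plus]; pm <- p[!plus]
    if (length(im) > 0L) {
      b0 <- substring(s, pm + 1, pm + 1)
      if (any(b0 != "G"))
        stop(sprintf("call_context: position not a C at %s:%d (-)", cn, pm[b0 != "G"][1]),
             call. = FALSE)
      ok <- pm - 2 >= 0
      b1 <- substring(s, pm, pm)          # forward base at p-1
      b2 <- substring(s, pm - 1, pm - 1)  # forward base at p-2
      ctx <- ifelse(b1 == "C", "CG", ifelse(b2 == "C", "CHG", "CHH"))
      out[im] <- ifelse(ok, ctx, NA_character_)
    }
  }
  out
}

#' Low-copy flanks of repeat copies
#'
#' For each repeat copy, the two `flank_bp` intervals adjacent to its edges,
#' emitted only if the flank overlaps no annotated repeat at all (strict
#' "absence of repetitive sequences") and lies fully within the chromosome.
#'
#' @param repeats repeat table
#' @param flank_bp flank width (default 1000)
#' @param chrom_lengths named vector of chromosome lengths
#' @return data.table chrom, start, end, copy_id, family_id, side
#' @export
low_copy_flanks <- function(repeats, flank_bp = 1000L, chrom_lengths) {
  stopifnot(flank_bp > 0)
  fl <- data.table::rbindlist(list(
    repeats[, .(chrom, start = start - flank_bp, end = start, copy_id, family_id,
                side = "5prime")],
    repeats[, .(chrom, start = end, end = end + flank_bp, copy_id, family_id,
                side = "3prime")]))
  fl <- fl[start >= 0 & end <= chrom_lengths[chrom]]
  if (nrow(fl) == 0L) return(fl)
  ov <- GenomicRanges::countOverlaps(to_granges(fl), to_granges(repeats))
  fl[ov == 0L]
}

#' Percent methylation by context over a region set
#'
#' Weighted (summed-count) definition: per context,
#' `pct = 100 * sum(meth_count) / sum(total_count)` over all cytosines
#' falling in the regions (both strands). A context with no covered
#' cytosines has `NA` pct, not 0. With `per_site = TRUE` a per-cytosine
#' binary mode is used instead: a site counts as methylated when
#' `meth_count / total_count >= 0.5` at coverage >= 3.
#'
#' @param records cytosine table from [read_cytosine_report()]
#' @param regions data.table with chrom, start, end (0-based half-open)
#' @param per_site use the binary per-site definition
#' @return data.table context, meth_c, total_c, pct (one row per context)
#' @export
region_methylation <- function(records, regions, per_site = FALSE) {
  ctxs <- c("CG", "CHG", "CHH")
  empty <- data.table::data.table(context = ctxs, meth_c = 0, total_c = 0,
                                  pct = NA_real_)
  if (nrow(regions) == 0L || nrow(records) == 0L) return(empty)
  ov <- GenomicRanges::findOverlaps(point_granges(records$chrom, records$position),
                                    to_granges(regions))
  hit <- records[unique(S4Vectors::queryHits(ov))]
  if (nrow(hit) == 0L) return(empty)
  if (per_site) {
    hit <- hit[total_count >= 3L]
    agg <- hit[, .(meth_c = sum(meth_count / total_count >= 0.5), total_c = .N),
               by = context]
  } else {
    agg <- hit[, .(meth_c = sum(meth_count), total_c = sum(total_count)), by = context]
  }
  out <- agg[data.table::data.table(context = ctxs), on = "context"]
  out[is.na(total_c), `:=`(meth_c = 0, total_c = 0)]
  out[, pct := ifelse(total_c > 0, 100 * meth_c / total_c, NA_real_)]
  out[]
}

#' Flank and internal methylation for one family
#'
#' @inheritParams region_methylation
#' @param repeats full repeat table (all families; needed to enforce
#'   low-copy flank eligibility)
#' @param family_id family to summarize
#' @param flank_bp flank width
#' @param chrom_lengths named chromosome lengths
#' @return list with `flank` and `internal` context summaries
#' @export
family_flank_and_internal <- function(records, repeats, family_id,
                                      flank_bp = 1000L, chrom_lengths,
                                      per_site = FALSE) {
  stopifnot(flank_bp > 0)
  fid <- family_id
  copies <- repeats[repeats$family_id == fid]
  if (nrow(copies) == 0L)
    stop(sprintf("family_flank_and_internal: unknown family '%s'", fid), call. = FALSE)
  fl <- low_copy_flanks(copies, flank_bp, chrom_lengths)
  if (nrow(fl) > 0L) {
    ov <- GenomicRanges::countOverlaps(to_granges(fl), to_granges(repeats))
    fl <- fl[ov == 0L]
  }
  list(flank = region_methylation(records, fl, per_site = per_site),
       internal = region_methylation(records, copies, per_site = per_site))
}

#' Random genomic region methylation baseline
#'
#' @inheritParams region_methylation
#' @param chrom_lengths named chromosome lengths
#' @param n_regions number of random regions (default 10000)
#' @param region_bp region width (default 1000)
#' @param seed RNG seed
#' @return context summary data.table (as [region_methylation()])
#' @export
random_region_baseline <- function(records, chrom_lengths, n_regions = 10000L,
                                   region_bp = 1000L, seed = 1L,
                                   per_site = FALSE) {
  stopifnot(n_regions >= 1)
  set.seed(seed)
  w <- as.numeric(pmax(chrom_lengths - region_bp, 1))
  ci <- sample.int(length(chrom_lengths), n_regions, replace = TRUE, prob = w)
  start <- floor(runif(n_regions) * w[ci])
  regions <- data.table::data.table(chrom = names(chrom_lengths)[ci],
                                    start = as.integer(start),
                                    end = as.integer(start + region_bp))
  region_methylation(records, regions, per_site = per_site)
}

#' Compare family-level methylation between spreading groups
#'
#' Two-sided Wilcoxon rank-sum of each group's per-family values against the
#' non-spreading group, significance at `alpha` (default 0.001, as
#' published).
#'
#' @param values_by_class named list of per-family numeric values, must
#'   include an element named `"non_spreading"`
#' @param alpha significance threshold
#' @return data.table group, n_group, n_ref, statistic, p_value, significant
#' @export
compare_groups <- function(values_by_class, alpha = 0.001) {
  if (!"non_spreading" %in% names(values_by_class))
    stop("compare_groups: reference group 'non_spreading' missing", call. = FALSE)
  ref <- values_by_class[["non_spreading"]]
  grps <- setdiff(names(values_by_class), "non_spreading")
  out <- lapply(grps, function(g) {
    x <- values_by_class[[g]]
    if (length(x) < 2L || length(ref) < 2L)
      return(data.table::data.table(group = g, n_group = length(x),
                                    n_ref = length(ref), statistic = NA_real_,
                                    p_value = NA_real_, significant = NA))
    wt <- suppressWarnings(stats::wilcox.test(x, ref, alternative = "two.sided"))
    data.table::data.table(group = g, n_group = length(x), n_ref = length(ref),
                           statistic = unname(wt$statistic), p_value = wt$p.value,
                           significant = wt$p.value < alpha)
  })
  data.table::rbindlist(out)
}

#' Chromosome-relative positional profile of flank methylation
#'
#' Each repeat copy is mapped to its relative chromosome position
#' (midpoint / chromosome length); its flank percent methylation is averaged
#' per class x window x context.
#'
#' @inheritParams region_methylation
#' @param repeats repeat table
#' @param classes data.table (family_id, class)
#' @param chrom_lengths named chromosome lengths
#' @param n_windows number of relative-position windows (default 20)
#' @param flank_bp flank width for per-copy flank methylation
#' @return data.table class, window, context, mean_pct, n_copies
#' @export
positional_profile <- function(records, repeats, classes, chrom_lengths,
                               n_windows = 20L, flank_bp = 1000L) {
  rp <- classes[repeats, on = "family_id", nomatch = 0L]
  fl <- low_copy_flanks(rp, flank_bp, chrom_lengths)
  if (nrow(fl) == 0L)
    return(data.table::data.table(class = character(), window = integer(),
                                  context = character(), mean_pct = double(),
                                  n_copies = integer()))
  per_copy <- fl[, {
    s <- region_methylation(records, .SD)
    .(context = s$context, pct = s$pct)
  }, by = .(copy_id, family_id)]
  rp[, `:=`(rel_pos = pmin(floor((start + end) / 2) / chrom_lengths[chrom], 1 - 1e-9))]
  rp[, window := as.integer(floor(rel_pos * n_windows)) + 1L]
  per_copy <- rp[, .(copy_id, class, window)][per_copy, on = "copy_id", nomatch = 0L]
  per_copy[!is.na(pct),
           .(mean_pct = mean(pct), n_copies = .N), by = .(class, window, context)][
             order(class, context, window)]
}
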