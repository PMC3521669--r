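# Probe-to-repeat assignment and family-level distance-binned enrichment
# profiles. Distances run from the probe midpoint to the nearest repeat edge;
# both flanks of a repeat are collapsed into one distance axis.

#' Assign single-copy probes to their closest repeat
#'
#' Each probe is assigned to the unique closest repeat (ties broken by
#' (chrom, start, copy_id) order). Probes farther than `max_distance_bp`
#' from every repeat are excluded. Probes whose midpoint falls inside a
#' repeat get `side = "internal"` (distance 0) and are excluded from flank
#' profiles downstream.
#'
#' @param probes probe table (probe_id, chrom, start, end, single_copy);
#'   only single-copy probes are used
#' @param repeats repeat table from [read_repeats()]
#' @param max_distance_bp retention cap on distance (default 5000, i.e.
#'   probes within 5 kb of a repeat are retained)
#' @return data.table probe_id, repeat_copy_id, family_id, distance_bp, side
#' @export
assign_probes <- function(probes, repeats, max_distance_bp = 5000L) {
  stopifnot(max_distance_bp > 0)
  if (nrow(repeats) == 0L) stop("assign_probes: empty repeat list", call. = FALSE)
  check_cols(probes, c("probe_id", "chrom", "start", "end", "single_copy"),
             "assign_probes")
  pr <- probes[single_copy == TRUE]
  if (!"midpoint" %in% names(pr)) pr <- pr[, midpoint := probe_midpoint(start, end)]
  rp <- data.table::copy(repeats)
  data.table::setorder(rp, chrom, start, copy_id)
  rp[, dist_idx := .I]
  pts <- point_granges(pr$chrom, pr$midpoint)
  rgr <- to_granges(rp)
  dtn <- GenomicRanges::distanceToNearest(pts, rgr)
  d0 <- rep(NA_integer_, nrow(pr))
  d0[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
  ok <- which(!is.na(d0))
  # distanceToNearest returns one arbitrary hit; re-enumerate every repeat
  # at exactly the nearest distance so ties break deterministically by
  # (chrom, start, copy_id)
  win <- GenomicRanges::GRanges(pr$chrom[ok],
                                IRanges::IRanges(start = pmax(pr$midpoint[ok] - d0[ok], 1L),
                                                 end = pr$midpoint[ok] + d0[ok] + 2L))
  ov <- GenomicRanges::findOverlaps(win, rgr)
  h <- data.table::data.table(q = ok[S4Vectors::queryHits(ov)],
                              s = S4Vectors::subjectHits(ov))
  m <- pr$midpoint[h$q]
  s0 <- rp$start[h$s]; e0 <- rp$end[h$s]
  h[, d := data.table::fifelse(m >= s0 & m < e0, 0L,
                               data.table::fifelse(m < s0, s0 - 1L - m, m - e0))]
  h <- h[d == d0[q]]
  dup <- h[, .N, by = q][N > 1L, q]
  if (length(dup) > 0L)
    message(sprintf("assign_probes: %d probe(s) equidistant from multiple repeats; tie broken by (chrom, start, copy_id)",
                    length(dup)))
  h <- h[order(q, s)][, .SD[1L], by = q]
  out <- data.table::data.table(
    probe_id = pr$probe_id[h$q],
    repeat_copy_id = rp$copy_id[h$s],
    family_id = rp$family_id[h$s],
    distance_bp = as.integer(h$d),
    mid = pr$midpoint[h$q],
    rstart = rp$start[h$s], rend = rp$end[h$s])
  out[, side := data.table::fifelse(mid >= rstart & mid < rend, "internal",
                                    data.table::fifelse(mid < rstart, "5prime", "3prime"))]
  out[side == "internal", distance_bp := 0L]
  out <- out[distance_bp <= max_distance_bp,
             .(probe_id, repeat_copy_id, family_id, distance_bp, side)]
  out[]
}

#' Distance bin index (half-open 200 bp bins, 1-based)
#'
#' Bin k aggregates distances in `[bin_width_bp * (k - 1), bin_width_bp * k)`,
#' i.e. `floor(distance / width) + 1`.
#'
#' @param distance_bp non-negative distance(s)
#' @param bin_width_bp bin width (default 200)
#' @return integer bin index/indices
#' @export
bin_index <- function(distance_bp, bin_width_bp = 200L) {
  if (any(distance_bp < 0)) stop("bin_index: negative distance", call. = FALSE)
  stopifnot(bin_width_bp > 0)
  as.integer(distance_bp %/% bin_width_bp) + 1L
}

# Replicate-averaged probe values for one (mark, genotype, tissue) sample.
replicate_means <- function(signals, mark_, genotype_ = NULL, tissue_ = NULL) {
  s <- signals[mark == mark_]
  if (!is.null(genotype_)) s <- s[genotype == genotype_]
  if (!is.null(tissue_)) s <- s[tissue == tissue_]
  s[, .(value = mean(log_ratio)), by = probe_id]
}

#' Binned mean enrichment profile for one family
#'
#' Bin means are arithmetic means over replicate-averaged probe values, both
#' flanks pooled; bins with no probes carry `NA`.
#'
#' @param assignments output of [assign_probes()]
#' @param signals long signal table
#' @param family_id family to profile
#' @param mark,genotype,tissue sample selectors
#' @param profile_window_bp flank window (default 4000)
#' @param bin_width_bp bin width (default 200)
#' @return data.table family_id, mark, genotype, tissue, bin_index,
#'   bin_start_bp, bin_end_bp, mean_log_ratio, probe_count
#' @export
family_profile <- function(assignments, signals, family_id, mark,
                           genotype = NULL, tissue = NULL,
                           profile_window_bp = 4000L, bin_width_bp = 200L) {
  fid <- family_id
  if (!fid %in% assignments$family_id)
    stop(sprintf("family_profile: unknown family '%s'", fid), call. = FALSE)
  profile_matrix(assignments, signals, marks = mark, genotype = genotype,
                 tissue = tissue, min_probes = 1L,
                 profile_window_bp = profile_window_bp,
                 bin_width_bp = bin_width_bp)[family_id == fid]
}

#' Family-by-bin profile matrix for one or more marks
#'
#' Families are emitted only if the number of assigned flanking probes
#' within `profile_window_bp` is at least `min_probes` (the published filter
#' is 1000 probes within the adjacent 4 kb).
#'
#' @inheritParams family_profile
#' @param marks character vector of marks to profile
#' @param min_probes minimum assigned flanking probes per family
#' @return long data.table, one row per family x mark x bin
#' @export
profile_matrix <- function(assignments, signals, marks, genotype = NULL,
                           tissue = NULL, min_probes = 1000L,
                           profile_window_bp = 4000L, bin_width_bp = 200L) {
  stopifnot(min_probes >= 1)
  K <- as.integer(profile_window_bp %/% bin_width_bp)
  fl <- assignments[side != "internal" & distance_bp < profile_window_bp]
  fl <- data.table::copy(fl)[, bin := bin_index(distance_bp, bin_width_bp)]
  keep_fams <- fl[, .N, by = family_id][N >= min_probes, family_id]
  fl <- fl[family_id %in% keep_fams]
  if (nrow(fl) == 0L) {
    return(data.table::data.table(family_id = character(), mark = character(),
                                  genotype = character(), tissue = character(),
                                  bin_index = integer(), bin_start_bp = integer(),
                                  bin_end_bp = integer(), mean_log_ratio = double(),
                                  probe_count = integer()))
  }
  grid <- data.table::CJ(family_id = sort(unique(fl$family_id)), bin_index = 1:K)
  out <- lapply(marks, function(m) {
    vals <- replicate_means(signals, m, genotype, tissue)
    x <- vals[fl, on = "probe_id", nomatch = 0L]
    agg <- x[, .(mean_log_ratio = mean(value), probe_count = .N),
             by = .(family_id, bin_index = bin)]
    full <- agg[grid, on = c("family_id", "bin_index")]
    full[is.na(probe_count), probe_count := 0L]
    full[, `:=`(mark = m,
                genotype = if (is.null(genotype)) NA_character_ else genotype,
                tissue = if (is.null(tissue)) NA_character_ else tissue,
                bin_start_bp = (bin_index - 1L) * bin_width_bp,
                bin_end_bp = bin_index * bin_width_bp)]
    full
  })
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("family_id", "mark", "genotype", "tissue",
                                 "bin_index", "bin_start_bp", "bin_end_bp",
                                 "mean_log_ratio", "probe_count"))
  data.table::setorder(res, mark, family_id, bin_index)
  res[]
}
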