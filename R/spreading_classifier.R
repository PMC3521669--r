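# Permutation-null classification of spreading families.
#
# The null is built from randomly placed zero-length pseudo-insertions
# (default 10,000). For each pseudo-insertion, probes within the profile
# window are binned exactly like real repeat flanks (both sides of the point
# collapsed). A family's per-bin observed mean is compared against B
# resampled null means of matched family size; the empirical p-value uses
# the add-one (Phipson-Smyth) form so p = 0 is impossible and alpha = 0.001
# is attainable only for B >= 1000. A family spreads when every one of the
# first `required_bins` bins (800 bp at 200 bp bins) is significant.

#' Generate randomly placed pseudo-insertions with binned probe values
#'
#' Sites are zero-length insertion points drawn uniformly from the union of
#' the chromosome spans that carry probes. Probes on both sides of each
#' point are binned by distance exactly as real repeat flanks are.
#'
#' @param probes probe table (single-copy probes are used)
#' @param signals long signal table
#' @param marks marks to precompute bin values for
#' @param n_sites number of pseudo-insertions (default 10000)
#' @param seed RNG seed
#' @param genotype,tissue sample selectors
#' @param profile_window_bp,bin_width_bp binning parameters
#' @return object of class `null_sites`: list with `sites` (data.table),
#'   per-mark `sum`/`count` matrices (n_sites x K) of per-site binned probe
#'   value sums and probe counts, and the generation parameters
#' @export
generate_null_sites <- function(probes, signals, marks, n_sites = 10000L,
                                seed = 1L, genotype = NULL, tissue = NULL,
                                profile_window_bp = 4000L, bin_width_bp = 200L) {
  stopifnot(n_sites >= 100)
  pr <- probes[single_copy == TRUE]
  if (nrow(pr) == 0L) stop("generate_null_sites: no probe-bearing space", call. = FALSE)
  if (!"midpoint" %in% names(pr)) pr <- data.table::copy(pr)[, midpoint := probe_midpoint(start, end)]
  spans <- pr[, .(lo = min(start), hi = max(end)), by = chrom]
  spans[, w := as.numeric(hi - lo)]
  set.seed(seed)
  ci <- sample.int(nrow(spans), n_sites, replace = TRUE, prob = spans$w)
  pos <- spans$lo[ci] + floor(runif(n_sites) * spans$w[ci])
  sites <- data.table::data.table(site_id = seq_len(n_sites),
                                  chrom = spans$chrom[ci], pos = as.integer(pos))
  K <- as.integer(profile_window_bp %/% bin_width_bp)
  # probes within the window on either side of each insertion point
  win <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(start = pmax(sites$pos - profile_window_bp + 1L, 1L),
                                                 end = sites$pos + profile_window_bp))
  pts <- point_granges(pr$chrom, pr$midpoint)
  ov <- GenomicRanges::findOverlaps(win, pts)
  pairs <- data.table::data.table(site = S4Vectors::queryHits(ov),
                                  probe = S4Vectors::subjectHits(ov))
  m <- pr$midpoint[pairs$probe]
  p0 <- sites$pos[pairs$site]
  # distance to the insertion point: right flank m >= pos -> m - pos,
  # left flank m < pos -> pos - 1 - m (both give 0 when abutting)
  pairs[, distance_bp := ifelse(m >= p0, m - p0, p0 - 1L - m)]
  pairs <- pairs[distance_bp < profile_window_bp]
  pairs[, bin := bin_index(distance_bp, bin_width_bp)]
  pairs[, probe_id := pr$probe_id[probe]]
  sums <- list(); counts <- list()
  for (mk in marks) {
    vals <- replicate_means(signals, mk, genotype, tissue)
    x <- vals[pairs, on = "probe_id", nomatch = 0L]
    S <- matrix(0, n_sites, K); C <- matrix(0L, n_sites, K)
    agg <- x[, .(s = sum(value), n = .N), by = .(site, bin)]
    S[cbind(agg$site, agg$bin)] <- agg$s
    C[cbind(agg$site, agg$bin)] <- agg$n
    sums[[mk]] <- S; counts[[mk]] <- C
  }
  structure(list(sites = sites, sum = sums, count = counts, marks = marks,
                 n_sites = n_sites, seed = seed,
                 profile_window_bp = profile_window_bp,
                 bin_width_bp = bin_width_bp),
            class = "null_sites")
}

#' Add-one empirical p-value (enrichment, one-sided)
#'
#' `p = (1 + #\{null >= observed\}) / (B + 1)`.
#'
#' @param observed_mean observed statistic
#' @param null_means resampled null statistics
#' @return empirical p in (0, 1]
#' @export
empirical_p <- function(observed_mean, null_means) {
  null_means <- null_means[!is.na(null_means)]
  if (length(null_means) == 0L) stop("empirical_p: empty null", call. = FALSE)
  (1 + sum(null_means >= observed_mean)) / (length(null_means) + 1)
}

#' Resampled null distribution of a family-size-matched bin mean
#'
#' Each of the B null means is the probe-count-weighted mean of the bin
#' values of `family_size` pseudo-insertions sampled with replacement,
#' i.e. the pooled-probe mean the observed family statistic uses.
#'
#' @param null_sites object from [generate_null_sites()]
#' @param mark which mark's bin values to use
#' @param family_size number of pseudo-insertions per resample (match the
#'   family's copy number)
#' @param bin which bin
#' @param B number of resamples (>= 1000 for alpha = 0.001)
#' @param seed RNG seed
#' @return numeric vector of B null means (draws with no probes are NA)
#' @export
family_bin_null <- function(null_sites, mark, family_size, bin, B = 10000L,
                            seed = 1L) {
  stopifnot(inherits(null_sites, "null_sites"), family_size >= 1, B >= 1)
  S <- null_sites$sum[[mark]][, bin]
  C <- null_sites$count[[mark]][, bin]
  if (all(C == 0L))
    stop(sprintf("family_bin_null: bin %d has no probes across pseudo-sites", bin),
         call. = FALSE)
  set.seed(seed)
  idx <- matrix(sample.int(null_sites$n_sites, B * family_size, replace = TRUE),
                nrow = B)
  num <- rowSums(matrix(S[idx], nrow = B))
  den <- rowSums(matrix(C[idx], nrow = B))
  ifelse(den > 0, num / den, NA_real_)
}

#' Classify one family from its per-bin p-values
#'
#' `spreading_both` iff every one of the first `required_bins` p-values is
#' `< alpha` for both 5mC and H3K9me2; `spreading_H3K9` iff H3K9me2 passes
#' and 5mC does not; `non_spreading` otherwise; `unclassifiable` if any
#' required p-value is missing. Inequality is strict, as published
#' (p < 0.001).
#'
#' @param p_meth,p_h3k9 per-bin p-values (bins 1..required_bins at least)
#' @param alpha significance threshold (default 0.001)
#' @param required_bins number of consecutive significant bins required
#'   (default 4, i.e. 800 bp of 200 bp bins)
#' @return one of "spreading_both", "spreading_H3K9", "non_spreading",
#'   "unclassifiable"
#' @export
classify_family <- function(p_meth, p_h3k9, alpha = 0.001, required_bins = 4L) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(p_meth) < required_bins || length(p_h3k9) < required_bins)
    stop("classify_family: p-value lists shorter than required_bins", call. = FALSE)
  pm <- p_meth[seq_len(required_bins)]
  ph <- p_h3k9[seq_len(required_bins)]
  if (anyNA(pm) || anyNA(ph)) return("unclassifiable")
  meth_ok <- all(pm < alpha)
  h3k9_ok <- all(ph < alpha)
  if (meth_ok && h3k9_ok) "spreading_both"
  else if (h3k9_ok) "spreading_H3K9"
  else "non_spreading"
}

#' Classify all profiled families against the permutation null
#'
#' H3K27me3 p-values (when the mark is present in both the profiles and the
#' null) are computed and reported but never used for classification; the
#' mark is a negative control.
#'
#' @param profiles output of [profile_matrix()] covering marks 5mC and
#'   H3K9me2 (and optionally H3K27me3)
#' @param null_sites object from [generate_null_sites()]
#' @param family_sizes data.table (family_id, n_copies) or named vector of
#'   copy numbers used to match resample size
#' @param alpha,required_bins classification rule parameters
#' @param B resamples per family/bin
#' @param seed base seed; per-(family, mark, bin) seeds are derived from it
#' @return data.table: family_id, class, then p_<mark>_bin<k> columns
#' @export
classify_all <- function(profiles, null_sites, family_sizes, alpha = 0.001,
                         required_bins = 4L, B = 10000L, seed = 1L) {
  stopifnot(B >= 1000)
  if (is.data.frame(family_sizes))
    family_sizes <- setNames(family_sizes$n_copies, family_sizes$family_id)
  fams <- sort(unique(profiles$family_id))
  marks <- intersect(c("5mC", "H3K9me2", "H3K27me3"),
                     intersect(unique(profiles$mark), null_sites$marks))
  if (!all(c("5mC", "H3K9me2") %in% marks))
    stop("classify_all: profiles/null must cover marks 5mC and H3K9me2", call. = FALSE)
  pv <- data.table::CJ(family_id = fams, mark = marks, bin = seq_len(required_bins))
  pv[, p_value := NA_real_]
  mark_catalog <- c("5mC", "H3K9me2", "H3K27me3")
  for (i in seq_along(fams)) {
    fs <- family_sizes[[fams[i]]]
    if (is.null(fs) || is.na(fs))
      stop(sprintf("classify_all: no copy number for family '%s'", fams[i]), call. = FALSE)
    for (mk in marks) {
      obs <- profiles[family_id == fams[i] & mark == mk][order(bin_index)]
      for (b in seq_len(required_bins)) {
        # positional child seed: stable under dropping/reordering marks
        counter <- (i * 4L + match(mk, mark_catalog)) * 64L + b
        o <- obs[bin_index == b]
        if (nrow(o) == 0L || is.na(o$mean_log_ratio) || o$probe_count == 0L) next
        nm <- family_bin_null(null_sites, mk, fs, b, B = B,
                              seed = derive_seed(seed, counter))
        pv[family_id == fams[i] & mark == mk & bin == b,
           p_value := empirical_p(o$mean_log_ratio, nm)]
      }
    }
  }
  cls <- vapply(fams, function(f) {
    classify_family(pv[family_id == f & mark == "5mC"][order(bin), p_value],
                    pv[family_id == f & mark == "H3K9me2"][order(bin), p_value],
                    alpha = alpha, required_bins = required_bins)
  }, "")
  wide <- data.table::dcast(pv, family_id ~ mark + bin, value.var = "p_value")
  nm <- names(wide)[-1]
  data.table::setnames(wide, nm, paste0("p_", sub("_(\\d+)$", "_bin\\1", nm)))
  out <- data.table::data.table(family_id = fams, class = unname(cls))[wide, on = "family_id"]
  out[]
}
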