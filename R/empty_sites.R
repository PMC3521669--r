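# Detection of TE insertions absent from a query haplotype ("empty sites")
# from whole-genome read alignments against the reference, and differential
# methylation of the nearest single-copy probe between genotypes with and
# without the insertion.
#
# Read-evidence criteria for a supporting read at a boundary (all must
# hold): > min_outside bp aligned in the low-copy flank outside the repeat;
# identity >= min_identity; the junction-side unaligned overhang
# > min_overhang bp and anchored within +/- boundary_tol bp of the annotated
# repeat edge; the opposite-side unaligned tail <= max_tail bp. A site is
# empty when >= min_support supporting reads and zero junction-covering
# reads are found.

#' Default empty-site detection parameters (published values)
#' @return named list: min_support 3, min_outside 50, min_identity 94,
#'   max_tail 20, min_overhang 20, boundary_tol 3
#' @export
empty_site_params <- function() {
  list(min_support = 3L, min_outside = 50L, min_identity = 94,
       max_tail = 20L, min_overhang = 20L, boundary_tol = 3L)
}

# Vectorized clause evaluation over alignment rows for a single boundary
# position. bpos = repeat start (5prime) or repeat end (3prime), 0-based.
supporting_clauses <- function(aln, bpos, boundary, params) {
  a <- aln$ref_start; b <- aln$ref_end
  tol <- params$boundary_tol
  if (boundary == "5prime") {
    outside <- pmin(b, bpos) - a          # aligned bases left of the repeat
    overhang <- aln$right_unaligned       # junction-side clip
    tail <- aln$left_unaligned
    anchored <- abs(b - bpos) <= tol      # alignment end at the boundary
  } else {
    outside <- b - pmax(a, bpos)
    overhang <- aln$left_unaligned
    tail <- aln$right_unaligned
    anchored <- abs(a - bpos) <= tol
  }
  data.table::data.table(
    outside_ok = outside > params$min_outside,
    identity_ok = aln$identity_pct >= params$min_identity,
    overhang_ok = overhang > params$min_overhang,
    anchored_ok = anchored,
    tail_ok = tail <= params$max_tail)
}

#' Evaluate one alignment as a supporting read for an empty boundary
#'
#' @param aln a one-row alignment table (as from [read_alignments()])
#' @param repeat_row a one-row repeat table
#' @param boundary `"5prime"` (repeat start) or `"3prime"` (repeat end)
#' @param params list as from [empty_site_params()]
#' @return logical verdict with a `trace` attribute naming each clause
#' @export
supporting_read <- function(aln, repeat_row, boundary = c("5prime", "3prime"),
                            params = empty_site_params()) {
  boundary <- match.arg(boundary)
  stopifnot(nrow(aln) == 1L, nrow(repeat_row) == 1L)
  if (aln$chrom != repeat_row$chrom) {
    v <- FALSE
    attr(v, "trace") <- c(same_chrom = FALSE)
    return(v)
  }
  bpos <- if (boundary == "5prime") repeat_row$start else repeat_row$end
  tr <- supporting_clauses(aln, bpos, boundary, params)
  v <- all(unlist(tr))
  attr(v, "trace") <- unlist(tr[1])
  v
}

#' Does an alignment cover the flank/repeat junction?
#'
#' True iff the aligned span has more than `tolerance_bp` aligned bases on
#' both sides of the boundary (alignments penetrating at most the anchor
#' tolerance into the repeat do not count as junction evidence).
#'
#' @inheritParams supporting_read
#' @param tolerance_bp penetration tolerance (default 3)
#' @return logical
#' @export
junction_covered <- function(aln, repeat_row, boundary = c("5prime", "3prime"),
                             tolerance_bp = 3L) {
  boundary <- match.arg(boundary)
  if (aln$chrom != repeat_row$chrom) return(FALSE)
  bpos <- if (boundary == "5prime") repeat_row$start else repeat_row$end
  (bpos - aln$ref_start) > tolerance_bp & (aln$ref_end - bpos) > tolerance_bp
}

#' Detect empty sites (TE insertions absent from the query haplotype)
#'
#' Per repeat copy and boundary, counts supporting and junction-covering
#' reads; a boundary is empty iff supporting reads >= `min_support` and no
#' junction read exists, occupied iff it has junction reads and no support,
#' else ambiguous (including conflicting evidence). The site-level status is
#' empty when one boundary is empty (`require_both_flanks = TRUE` demands
#' both).
#'
#' @param alignments alignment table (unique alignments only are used)
#' @param repeats repeat table
#' @param params list as from [empty_site_params()]
#' @param require_both_flanks demand empty evidence at both boundaries
#' @return data.table: repeat_copy_id, family_id, chrom, boundary_tested,
#'   n_supporting, n_junction, per-boundary counts and status
#' @export
detect_empty_sites <- function(alignments, repeats, params = empty_site_params(),
                               require_both_flanks = FALSE) {
  aln <- alignments[unique_aln == TRUE]
  # candidate alignments near each boundary: overlap repeat +/- max query len
  pad <- if (nrow(aln) > 0L) max(aln$query_length) else 0L
  agr <- to_granges(aln, start = aln$ref_start, end = aln$ref_end)
  res <- vector("list", nrow(repeats))
  rgr <- to_granges(repeats, start = pmax(repeats$start - pad, 0L),
                    end = repeats$end + pad)
  ov <- GenomicRanges::findOverlaps(rgr, agr)
  byrep <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  boundary_counts <- function(sub, rrow, boundary) {
    bpos <- if (boundary == "5prime") rrow$start else rrow$end
    sub <- sub[chrom == rrow$chrom]
    if (nrow(sub) == 0L) return(c(sup = 0L, jun = 0L))
    cl <- supporting_clauses(sub, bpos, boundary, params)
    sup <- sum(rowSums(as.matrix(cl)) == ncol(cl))
    jun <- sum((bpos - sub$ref_start) > params$boundary_tol &
                 (sub$ref_end - bpos) > params$boundary_tol)
    c(sup = sup, jun = jun)
  }
  for (i in seq_len(nrow(repeats))) {
    rrow <- repeats[i]
    sub <- aln[byrep[[as.character(i)]] %||% integer(0)]
    c5 <- boundary_counts(sub, rrow, "5prime")
    c3 <- boundary_counts(sub, rrow, "3prime")
    # supporting evidence is counted per site ("at least 3 reads supporting
    # the site"): a junction-spanning read contributes a supporting
    # alignment at each boundary of the same empty site
    sup <- c5["sup"] + c3["sup"]
    jun <- c5["jun"] + c3["jun"]
    empty <- if (require_both_flanks)
      c5["sup"] >= params$min_support && c3["sup"] >= params$min_support &&
        jun == 0L
    else sup >= params$min_support && jun == 0L
    status <- if (empty) "empty"
    else if (jun >= 1L && sup == 0L) "occupied"
    else "ambiguous"
    boundary_tested <- if (c5["sup"] > 0L && c3["sup"] > 0L) "both"
    else if (c5["sup"] > 0L) "5prime"
    else if (c3["sup"] > 0L) "3prime"
    else "both"
    res[[i]] <- data.table::data.table(
      repeat_copy_id = rrow$copy_id, family_id = rrow$family_id,
      chrom = rrow$chrom, start = rrow$start, end = rrow$end,
      boundary_tested = boundary_tested,
      n_supporting = as.integer(c5["sup"] + c3["sup"]),
      n_junction = as.integer(c5["jun"] + c3["jun"]),
      n_supporting_5p = as.integer(c5["sup"]), n_junction_5p = as.integer(c5["jun"]),
      n_supporting_3p = as.integer(c3["sup"]), n_junction_3p = as.integer(c3["jun"]),
      status = status)
  }
  data.table::rbindlist(res)
}

#' Nearest single-copy probe to an empty-site boundary
#'
#' @param sites data.table with chrom and a boundary position column `pos`
#' @param probes probe table (single-copy probes are used)
#' @param cap_bp maximum allowed distance (default 5000); farther sites are
#'   dropped with a message
#' @return `sites` with probe_id and probe_distance_bp columns (dropped rows
#'   removed)
#' @export
nearest_probe <- function(sites, probes, cap_bp = 5000L) {
  pr <- probes[single_copy == TRUE]
  if (!"midpoint" %in% names(pr)) pr <- data.table::copy(pr)[, midpoint := probe_midpoint(start, end)]
  data.table::setorder(pr, chrom, midpoint, probe_id)
  out <- data.table::copy(sites)
  out[, `:=`(probe_id = NA_character_, probe_distance_bp = NA_integer_)]
  for (cn in unique(out$chrom)) {
    p <- pr[chrom == cn]
    if (nrow(p) == 0L) next
    idx <- which(out$chrom == cn)
    for (i in idx) {
      d <- abs(p$midpoint - out$pos[i])
      j <- which(d == min(d))
      j <- j[order(p$probe_id[j])][1]   # deterministic tie-break by probe_id
      out$probe_id[i] <- p$probe_id[j]
      out$probe_distance_bp[i] <- d[j]
    }
  }
  drop <- is.na(out$probe_distance_bp) | out$probe_distance_bp > cap_bp
  if (any(drop))
    message(sprintf("nearest_probe: %d site(s) without a probe within %d bp dropped",
                    sum(drop), cap_bp))
  out[!drop]
}

#' Welch's unequal-variance two-sample t-test
#'
#' Hand-rolled so the permutation-free differential test is independent of
#' `stats::t.test` (which serves as the oracle in the test suite).
#'
#' @param x,y numeric vectors (>= 2 values each)
#' @return list(statistic, df, p_value, mean_x, mean_y)
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("welch_t: need >= 2 values per group", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = tt, df = df, p_value = 2 * stats::pt(-abs(tt), df),
       mean_x = mx, mean_y = my)
}

#' Differential methylation at a probe between genotypes
#'
#' Welch two-sample t-test on replicate log-ratios, two-sided; differential
#' iff p < alpha (default 0.01, as published for the empty-site
#' comparisons).
#'
#' @param signals long signal table
#' @param probe_id probe to test
#' @param genotype_with,genotype_without genotypes with/without the insertion
#' @param mark chromatin mark (default "5mC")
#' @param tissue optional tissue selector
#' @param alpha significance threshold
#' @return data.table probe_id, mean_with_insertion, mean_without, p_value,
#'   differential, direction
#' @export
test_differential <- function(signals, probe_id, genotype_with,
                              genotype_without, mark = "5mC", tissue = NULL,
                              alpha = 0.01) {
  pid <- probe_id; mk <- mark
  s <- signals[signals$probe_id == pid & signals$mark == mk]
  if (!is.null(tissue)) s <- s[s$tissue == tissue]
  x <- s[genotype == genotype_with, log_ratio]
  y <- s[genotype == genotype_without, log_ratio]
  if (length(x) < 2L || length(y) < 2L)
    stop(sprintf("test_differential: < 2 replicates for probe '%s'", pid), call. = FALSE)
  w <- welch_t(x, y)
  diff <- !is.na(w$p_value) && w$p_value < alpha
  data.table::data.table(
    probe_id = pid, mean_with_insertion = w$mean_x, mean_without = w$mean_y,
    p_value = w$p_value, differential = diff,
    direction = if (!diff) NA_character_
    else if (w$mean_x > w$mean_y) "higher_with_insertion" else "higher_without")
}

#' Summarize differential methylation at empty sites
#'
#' @param calls data.table of differential calls with a `class` column (the
#'   spreading class of the absent TE's family)
#' @param signals long signal table for the genome-wide background
#' @param probes probe table; all assayed single-copy probes enter the
#'   background
#' @param genotype_with,genotype_without genotypes as in
#'   [test_differential()]
#' @param mark,tissue,alpha as in [test_differential()]
#' @return list: `per_class` (class, n, n_differential, frac_differential),
#'   `frac_higher_with_insertion`, `genome_wide_frac_differential`
#' @export
summarize_empty_sites <- function(calls, signals, probes, genotype_with,
                                  genotype_without, mark = "5mC",
                                  tissue = NULL, alpha = 0.01) {
  per_class <- calls[, .(n = .N, n_differential = sum(differential)),
                     by = class][, frac_differential := n_differential / n][]
  nd <- calls[differential == TRUE]
  frac_higher <- if (nrow(nd) > 0L)
    mean(nd$direction == "higher_with_insertion") else NA_real_
  bg <- genome_wide_differential(signals, probes, genotype_with,
                                 genotype_without, mark, tissue, alpha)
  list(per_class = per_class, frac_higher_with_insertion = frac_higher,
       genome_wide_frac_differential = bg)
}

# Fraction of all assayed probes with differential signal between genotypes
# (vectorized Welch t over probes).
genome_wide_differential <- function(signals, probes, genotype_with,
                                     genotype_without, mark = "5mC",
                                     tissue = NULL, alpha = 0.01) {
  mk <- mark
  s <- signals[signals$mark == mk & signals$probe_id %in% probes$probe_id]
  if (!is.null(tissue)) s <- s[s$tissue == tissue]
  st <- s[genotype %in% c(genotype_with, genotype_without),
          .(m = mean(log_ratio), v = var(log_ratio), n = .N),
          by = .(probe_id, genotype)]
  wd <- data.table::dcast(st, probe_id ~ genotype, value.var = c("m", "v", "n"))
  cw <- function(p) paste0(p, "_", genotype_with)
  co <- function(p) paste0(p, "_", genotype_without)
  ok <- wd[[paste0("n_", genotype_with)]] >= 2 & wd[[paste0("n_", genotype_without)]] >= 2
  wd <- wd[ok]
  se2 <- wd[[cw("v")]] / wd[[cw("n")]] + wd[[co("v")]] / wd[[co("n")]]
  tt <- (wd[[cw("m")]] - wd[[co("m")]]) / sqrt(se2)
  df <- se2^2 / ((wd[[cw("v")]] / wd[[cw("n")]])^2 / (wd[[cw("n")]] - 1) +
                   (wd[[co("v")]] / wd[[co("n")]])^2 / (wd[[co("n")]] - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  mean(p < alpha, na.rm = TRUE)
}
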