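# Independent brute-force oracles used by unit and acceptance tests. These
# deliberately avoid the package's interval machinery.

# O(n*m) nearest-repeat assignment. Distances count the bases strictly
# between the probe midpoint and the repeat (0 = abutting), matching the
# package's convention; ties broken by (chrom, start, copy_id).
brute_nearest <- function(probes, repeats) {
  rp <- repeats[order(repeats$chrom, repeats$start, repeats$copy_id), ]
  out <- lapply(seq_len(nrow(probes)), function(i) {
    m <- probes$midpoint[i]
    best <- NULL
    for (j in seq_len(nrow(rp))) {
      if (rp$chrom[j] != probes$chrom[i]) next
      d <- if (m >= rp$start[j] && m < rp$end[j]) 0L
      else if (m < rp$start[j]) rp$start[j] - 1L - m
      else m - rp$end[j]
      side <- if (m >= rp$start[j] && m < rp$end[j]) "internal"
      else if (m < rp$start[j]) "5prime" else "3prime"
      if (is.null(best) || d < best$d) best <- list(d = d, j = j, side = side)
    }
    if (is.null(best)) return(NULL)
    data.frame(probe_id = probes$probe_id[i], repeat_copy_id = rp$copy_id[best$j],
               family_id = rp$family_id[best$j], distance_bp = best$d,
               side = best$side, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-base bitmap union coverage of interval set `cov` over interval [s, e)
brute_union_coverage <- function(cov, s, e) {
  hit <- rep(FALSE, e - s)
  for (j in seq_len(nrow(cov))) {
    a <- max(cov$start[j], s); b <- min(cov$end[j], e)
    if (a < b) hit[(a - s + 1):(b - s)] <- TRUE
  }
  sum(hit)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n+m, n) group assignments (no ties assumed).
exact_wilcox_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  all_r <- rank(c(x, y))
  combs <- utils::combn(nx + ny, nx)
  w_all <- apply(combs, 2, function(ix) sum(all_r[ix]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Regex context oracle on the forward-strand sequence string
regex_context <- function(seq_fwd, pos0, strand) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  tri <- if (strand == "+") substr(seq_fwd, pos0 + 1, pos0 + 3)
  else revcomp(substr(seq_fwd, pos0 - 1, pos0 + 1))
  if (nchar(tri) < 3) return(NA_character_)
  if (grepl("^CG", tri)) "CG"
  else if (grepl("^C[ACT]G", tri)) "CHG"
  else if (grepl("^C[ACT][ACT]", tri)) "CHH"
  else NA_character_
}

# Tiny deterministic simulated world shared by several unit tests
small_bundle <- function(seed = 42L, emit = c("signals", "reads"),
                         polymorphism_rate = 0.5) {
  set.seed(seed)
  fams <- synth_families(n_both = 2L, n_h3k9 = 1L, n_non = 2L,
                         n_copies_range = c(15L, 30L),
                         element_length_bp = 1500L,
                         polymorphism_rate = polymorphism_rate)
  cfg <- synth_config(chrom_lengths = c(chr1 = 6e5, chr2 = 6e5),
                      families = fams, genes = list(n_genes = 40L),
                      seed = seed)
  simulate_bundle(cfg, emit = emit)
}
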