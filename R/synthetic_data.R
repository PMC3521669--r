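# Self-consistent synthetic dataset with known ground truth: genome, TE
# annotation, single-copy probes with replicate log-ratio signals decaying
# exponentially into TE flanks, per-cytosine bisulfite counts, reads from a
# second haplotype with polymorphic TE insertions excised, genes whose
# expression is suppressed near spreading TEs, small RNAs and a family
# attribute table. Every emission is deterministic given the config seed.

#' Family specification table for the synthetic generator
#'
#' Defaults encode the conditions the classifier is meant to recover:
#' spreading amplitude A = 0.8 log2 units at distance 0 decaying as
#' exp(-d/lambda) with lambda = 600 bp (the observed spreading scale is
#' roughly 600-1600 bp); H3K9-only families share the H3K9me2 decay but
#' their 5mC component uses a short lambda_meth (150 bp) so methylation
#' enrichment dies out before 800 bp; non-spreading families have A = 0.
#' LINE superfamilies occur only among non-spreading families.
#'
#' @param n_both,n_h3k9,n_non family counts per true class
#' @param n_copies_range copies per family (sampled uniformly)
#' @param element_length_bp element length
#' @param A amplitude (log2 units at distance 0) for spreading marks
#' @param lambda_bp decay scale for spreading marks
#' @param lambda_meth_short_bp 5mC decay scale of H3K9-only families
#' @param polymorphism_rate fraction of copies absent from haplotype 2
#' @return data.table, one row per family
#' @export
synth_families <- function(n_both = 5L, n_h3k9 = 3L, n_non = 12L,
                           n_copies_range = c(20L, 100L),
                           element_length_bp = 3000L, A = 0.8,
                           lambda_bp = 600, lambda_meth_short_bp = 150,
                           polymorphism_rate = 0) {
  n <- n_both + n_h3k9 + n_non
  cls <- rep(c("spreading_both", "spreading_H3K9", "non_spreading"),
             c(n_both, n_h3k9, n_non))
  super <- character(n)
  super[cls == "spreading_both"] <- rep_len(c("RLG", "RLG", "RLC"), n_both)
  super[cls == "spreading_H3K9"] <- rep_len(c("RLC", "RLC", "RLG"), n_h3k9)
  super[cls == "non_spreading"] <- rep_len(c("RLG", "RLC", "RLX", "LINE"), n_non)
  data.table::data.table(
    family_id = sprintf("fam%02d", seq_len(n)),
    superfamily = super,
    n_copies = as.integer(round(seq(n_copies_range[1], n_copies_range[2],
                                    length.out = n))),
    element_length_bp = as.integer(element_length_bp),
    true_class = cls,
    A_meth = ifelse(cls == "non_spreading", 0, A),
    A_h3k9 = ifelse(cls == "non_spreading", 0, A),
    lambda_bp = lambda_bp,
    lambda_meth_bp = ifelse(cls == "spreading_H3K9", lambda_meth_short_bp,
                            lambda_bp),
    internal_CG = 0.9, internal_CHG = 0.8, internal_CHH = 0.05,
    polymorphism_rate = polymorphism_rate,
    smallrna_rate = 5,
    insertion_date = ifelse(cls == "spreading_both",
                            round(runif(n, 0.5, 2), 2),
                            round(runif(n, 0.5, 6), 2)))
}

#' Synthetic dataset configuration
#'
#' @param chrom_lengths named vector of chromosome lengths (default two
#'   5 Mb chromosomes)
#' @param families family table from [synth_families()]
#' @param probe_spacing_bp probe spacing (200 bp, the array design)
#' @param probe_length_bp probe footprint
#' @param n_replicates replicate log-ratio measurements per sample
#' @param noise_sd replicate Gaussian noise sd (log2 units)
#' @param baseline_log_ratio genome-wide mean log-ratio
#' @param marks marks to emit signals for
#' @param genotype_with,genotype_without reference genotype (carries every
#'   insertion) and query genotype (polymorphic copies absent)
#' @param tissue tissue label
#' @param bs bisulfite parameters: coverage_mean, baseline (named CG/CHG/CHH
#'   probabilities), sample_fraction
#' @param reads haplotype-2 read parameters: length_bp, coverage, error_rate
#' @param genes gene/expression parameters (see defaults in the function)
#' @param seed RNG seed
#' @return config list (class `synth_config`)
#' @export
synth_config <- function(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                         families = NULL,
                         probe_spacing_bp = 200L, probe_length_bp = 50L,
                         n_replicates = 3L, noise_sd = 0.5,
                         baseline_log_ratio = 0,
                         marks = c("5mC", "H3K9me2", "H3K27me3"),
                         genotype_with = "B73", genotype_without = "Mo17",
                         tissue = "leaf",
                         bs = list(), reads = list(), genes = list(),
                         seed = 1L) {
  bs <- utils::modifyList(list(coverage_mean = 7,
                               baseline = c(CG = 0.75, CHG = 0.55, CHH = 0.05),
                               sample_fraction = 1), bs)
  reads <- utils::modifyList(list(length_bp = 400L, coverage = 5,
                                  error_rate = 0), reads)
  genes <- utils::modifyList(list(n_genes = 200L, gene_length_bp = 2000L,
                                  n_exons = 2L, near_fraction = 0.7,
                                  max_tss_distance_bp = 5000L,
                                  mean_rpkm = 10, sdlog = 0.5,
                                  suppression_factor = 0.2,
                                  suppression_dist_bp = 500L,
                                  silent_prob_near = 0, silent_prob_far = 0,
                                  library_size = 2e7, sample_id = "leaf"), genes)
  if (is.null(families)) {
    set.seed(seed)
    families <- synth_families()
  }
  stopifnot(all(families$lambda_bp > 0), probe_spacing_bp > 0,
            all(bs$baseline >= 0 & bs$baseline <= 1),
            all(families$polymorphism_rate >= 0 & families$polymorphism_rate <= 1))
  structure(list(chrom_lengths = chrom_lengths, families = families,
                 probe_spacing_bp = as.integer(probe_spacing_bp),
                 probe_length_bp = as.integer(probe_length_bp),
                 n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
                 baseline_log_ratio = baseline_log_ratio, marks = marks,
                 genotype_with = genotype_with,
                 genotype_without = genotype_without, tissue = tissue,
                 bs = bs, reads = reads, genes = genes, seed = as.integer(seed)),
            class = "synth_config")
}

# Non-overlapping placement of intervals by iterative redraw.
place_intervals <- function(chrom_lengths, lengths, max_tries = 100L) {
  n <- length(lengths)
  wts <- as.numeric(chrom_lengths)
  ci <- sample.int(length(chrom_lengths), n, replace = TRUE, prob = wts)
  dt <- data.table::data.table(idx = seq_len(n), chrom = names(chrom_lengths)[ci],
                               len = as.integer(lengths))
  dt[, start := as.integer(floor(runif(.N) * (chrom_lengths[chrom] - len)))]
  for (try in seq_len(max_tries)) {
    data.table::setorder(dt, chrom, start)
    dt[, end := start + len]
    dt[, keep := start >= data.table::shift(cummax(end), fill = -1L), by = chrom]
    if (all(dt$keep)) break
    if (try == max_tries)
      stop("place_intervals: could not place intervals without overlap", call. = FALSE)
    redo <- which(!dt$keep)
    dt[redo, start := as.integer(floor(runif(length(redo)) *
                                         (chrom_lengths[chrom] - len)))]
  }
  data.table::setorder(dt, idx)
  dt[, .(chrom, start, end)]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a full synthetic dataset
#'
#' Signal model: for a probe at distance d from the nearest TE of family f,
#' the replicate log-ratio for mark m is
#' `baseline + A_{f,m} exp(-d / lambda_{f,m}) + N(0, noise_sd)` in the
#' genotype carrying the insertion; in the query genotype the decay term is
#' dropped for copies absent from haplotype 2. Bisulfite methylation
#' probabilities are raised by the same decay through a logistic link.
#' Haplotype-2 reads are drawn from the haplotype-2 sequence (polymorphic
#' copies excised) and mapped back analytically, so reads spanning an empty
#' junction carry a soft-clipped overhang anchored at the annotated repeat
#' edge and reads across retained insertions cover the junction.
#'
#' @param config a [synth_config()] object
#' @param emit which components to generate: subset of `"genome"`,
#'   `"signals"`, `"bisulfite"`, `"reads"`, `"expression"`, `"smallrna"`
#'   (repeats, probes and the truth manifest are always generated; the
#'   genome is generated whenever bisulfite or reads need it)
#' @return a `bundle` list: chrom_lengths, genome, repeats, probes, signals,
#'   cytosines, alignments, genes, exons, counts, libsizes, smallrna,
#'   attributes, truth
#' @export
simulate_bundle <- function(config,
                            emit = c("genome", "signals", "bisulfite",
                                     "reads", "expression", "smallrna")) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fams <- config$families
  cl <- config$chrom_lengths

  # --- repeats ------------------------------------------------------------
  copies <- fams[, .(family_id, n = n_copies, len = element_length_bp)][
    , .(len = rep(len, n)), by = family_id]
  placed <- place_intervals(cl, copies$len)
  repeats <- data.table::data.table(
    chrom = placed$chrom, start = placed$start, end = placed$end,
    strand = sample(c("+", "-"), nrow(placed), replace = TRUE),
    family_id = copies$family_id,
    superfamily = fams$superfamily[match(copies$family_id, fams$family_id)])
  data.table::setorder(repeats, chrom, start)
  repeats[, copy_id := sprintf("%s_c%04d", family_id, seq_len(.N)), by = family_id]
  prate <- fams$polymorphism_rate[match(repeats$family_id, fams$family_id)]
  repeats[, hap2_present := runif(.N) >= prate]

  # --- genome -------------------------------------------------------------
  need_genome <- any(c("genome", "bisulfite", "reads") %in% emit)
  genome <- NULL
  if (need_genome) {
    genome <- Biostrings::DNAStringSet(vapply(as.integer(cl), random_dna, ""))
    names(genome) <- names(cl)
  }

  # --- probes -------------------------------------------------------------
  plen <- config$probe_length_bp
  probes <- data.table::rbindlist(lapply(names(cl), function(cn) {
    st <- seq(0L, as.integer(cl[cn]) - plen, by = config$probe_spacing_bp)
    data.table::data.table(chrom = cn, start = as.integer(st),
                           end = as.integer(st + plen))
  }))
  ov <- GenomicRanges::countOverlaps(to_granges(probes), to_granges(repeats))
  probes <- probes[ov == 0L]
  probes[, probe_id := sprintf("p%07d", .I)]
  probes[, single_copy := TRUE]
  probes[, midpoint := probe_midpoint(start, end)]
  data.table::setcolorder(probes, c("probe_id", "chrom", "start", "end",
                                    "single_copy", "midpoint"))

  # assignment of probes to their closest copy drives both signals and truth
  asg <- assign_probes(probes, repeats, max_distance_bp = 5000L)
  asg <- merge(asg, repeats[, .(copy_id, hap2_present)],
               by.x = "repeat_copy_id", by.y = "copy_id")

  # --- signals ------------------------------------------------------------
  signals <- NULL
  if ("signals" %in% emit) {
    fi <- match(asg$family_id, fams$family_id)
    eff <- data.table::data.table(
      probe_id = asg$probe_id,
      hap2_present = asg$hap2_present,
      e_meth = fams$A_meth[fi] * exp(-asg$distance_bp / fams$lambda_meth_bp[fi]),
      e_h3k9 = fams$A_h3k9[fi] * exp(-asg$distance_bp / fams$lambda_bp[fi]))
    eff[asg$side == "internal", `:=`(e_meth = 0, e_h3k9 = 0)]
    base <- config$baseline_log_ratio
    grid <- data.table::CJ(probe_id = probes$probe_id, mark = config$marks,
                           genotype = c(config$genotype_with,
                                        config$genotype_without),
                           replicate = seq_len(config$n_replicates))
    grid <- eff[grid, on = "probe_id"]
    grid[is.na(e_meth), `:=`(e_meth = 0, e_h3k9 = 0, hap2_present = TRUE)]
    grid[, mu := base]
    grid[mark == "5mC" & (genotype == config$genotype_with | hap2_present),
         mu := base + e_meth]
    grid[mark == "H3K9me2" & (genotype == config$genotype_with | hap2_present),
         mu := base + e_h3k9]
    grid[, log_ratio := rnorm(.N, mu, config$noise_sd)]
    grid[, tissue := config$tissue]
    signals <- grid[, .(probe_id, mark, genotype, tissue, replicate, log_ratio)]
  }

  # --- bisulfite (reference genotype, all insertions present) -------------
  cytosines <- NULL
  if ("bisulfite" %in% emit) {
    cyt <- data.table::rbindlist(lapply(names(genome), function(cn) {
      s <- genome[[cn]]
      cpos <- Biostrings::start(Biostrings::matchPattern("C", s)) - 1L
      gpos <- Biostrings::start(Biostrings::matchPattern("G", s)) - 1L
      data.table::data.table(
        chrom = cn,
        position = c(cpos, gpos),
        strand = rep(c("+", "-"), c(length(cpos), length(gpos))))
    }))
    if (config$bs$sample_fraction < 1)
      cyt <- cyt[runif(.N) < config$bs$sample_fraction]
    cyt[, context := call_context(genome, chrom, position, strand)]
    cyt <- cyt[!is.na(context)]
    p0 <- config$bs$baseline[cyt$context]
    # internal vs flank status relative to the nearest repeat
    pts <- point_granges(cyt$chrom, cyt$position)
    dtn <- GenomicRanges::distanceToNearest(to_granges(cyt,
                                                       start = cyt$position,
                                                       end = cyt$position + 1L),
                                            to_granges(repeats))
    d <- rep(NA_real_, nrow(cyt))
    d[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
    nf <- rep(NA_integer_, nrow(cyt))
    nf[S4Vectors::queryHits(dtn)] <-
      match(repeats$family_id[S4Vectors::subjectHits(dtn)], fams$family_id)
    inside <- IRanges::overlapsAny(pts, to_granges(repeats))
    p <- as.numeric(p0)
    flank <- !inside & !is.na(d) & d < 4000
    p[flank] <- plogis(qlogis(p0[flank]) +
                         fams$A_meth[nf[flank]] *
                           exp(-d[flank] / fams$lambda_meth_bp[nf[flank]]))
    intn <- which(inside)
    icol <- paste0("internal_", cyt$context[intn])
    p[intn] <- as.numeric(as.matrix(fams[, .(internal_CG, internal_CHG,
                                             internal_CHH)])[
      cbind(nf[intn], match(icol, paste0("internal_",
                                         c("CG", "CHG", "CHH"))))])
    cov <- rpois(nrow(cyt), config$bs$coverage_mean)
    cyt[, total_count := cov]
    cyt[, meth_count := rbinom(.N, cov, p)]
    cytosines <- cyt[total_count > 0L]
  }

  # --- haplotype-2 reads --------------------------------------------------
  alignments <- NULL
  if ("reads" %in% emit) {
    alignments <- simulate_hap2_reads(repeats, cl, config)
  }

  # --- genes + expression -------------------------------------------------
  genes <- exons <- counts <- libsizes <- NULL
  if ("expression" %in% emit) {
    gx <- simulate_genes(repeats, fams, cl, config)
    genes <- gx$genes; exons <- gx$exons; counts <- gx$counts
    libsizes <- gx$libsizes
  }

  # --- small RNAs ---------------------------------------------------------
  smallrna <- NULL
  if ("smallrna" %in% emit) {
    rate <- fams$smallrna_rate[match(repeats$family_id, fams$family_id)]
    nr <- rpois(nrow(repeats), rate)
    ri <- rep(seq_len(nrow(repeats)), nr)
    if (length(ri) > 0L) {
      w <- 24L
      st <- repeats$start[ri] +
        floor(runif(length(ri)) * pmax(repeats$end[ri] - repeats$start[ri] - w, 1))
      smallrna <- data.table::data.table(chrom = repeats$chrom[ri],
                                         start = as.integer(st),
                                         end = as.integer(st + w))[order(chrom, start)]
    } else {
      smallrna <- data.table::data.table(chrom = character(), start = integer(),
                                         end = integer())
    }
  }

  # --- attributes and truth ----------------------------------------------
  attributes <- repeats[, .(copy_number = .N,
                            genome_mb = sum(end - start) / 1e6,
                            mean_fragment_length = mean(end - start)),
                        by = family_id]
  attributes <- merge(attributes,
                      fams[, .(family_id, superfamily, insertion_date)],
                      by = "family_id")
  data.table::setnames(attributes, "insertion_date", "mean_insertion_date")

  truth <- list(
    seed = config$seed,
    families = fams[, .(family_id, true_class, A_meth, A_h3k9, lambda_bp,
                        lambda_meth_bp, polymorphism_rate)],
    copies = repeats[, .(copy_id, family_id, chrom, start, end, hap2_present)],
    genes = if (!is.null(genes)) genes[, .(gene_id, suppressed, silent)] else NULL,
    params = list(noise_sd = config$noise_sd,
                  baseline_log_ratio = config$baseline_log_ratio,
                  suppression_factor = config$genes$suppression_factor,
                  suppression_dist_bp = config$genes$suppression_dist_bp,
                  read_coverage = config$reads$coverage,
                  bs_baseline = as.list(config$bs$baseline)))

  structure(list(chrom_lengths = cl, genome = genome, repeats = repeats,
                 probes = probes, signals = signals, cytosines = cytosines,
                 alignments = alignments,
                 genes = if (!is.null(genes))
                   genes[, .(gene_id, chrom, start, end, strand, exon_length_bp)]
                 else NULL,
                 exons = exons, counts = counts, libsizes = libsizes,
                 smallrna = smallrna, attributes = attributes, truth = truth,
                 config = config),
            class = "te_bundle")
}

# Reads drawn from haplotype 2 (polymorphic TE copies excised), mapped back
# to reference coordinates analytically. Reads spanning an excision junction
# align on their longer side with the remainder soft-clipped; the clip is
# anchored exactly at the annotated repeat edge.
simulate_hap2_reads <- function(repeats, chrom_lengths, config) {
  L <- as.integer(config$reads$length_bp)
  out <- list()
  rid <- 0L
  for (cn in names(chrom_lengths)) {
    clen <- as.integer(chrom_lengths[cn])
    exc <- repeats[chrom == cn & hap2_present == FALSE][order(start)]
    # collinear blocks of hap2 -> reference
    bstart <- c(0L, exc$end)                 # ref starts of blocks
    bend <- c(exc$start, clen)               # ref ends
    blen <- bend - bstart
    keep <- blen > 0L
    bstart <- bstart[keep]; bend <- bend[keep]; blen <- blen[keep]
    qstart <- cumsum(c(0L, head(blen, -1L))) # hap2 starts of blocks
    hlen <- sum(blen)
    n_reads <- as.integer(round(config$reads$coverage * hlen / L))
    if (n_reads == 0L) next
    q0 <- as.integer(floor(runif(n_reads) * (hlen - L)))
    bi <- findInterval(q0, qstart)
    off <- q0 - qstart[bi]
    room <- blen[bi] - off                     # hap2 bases left in the block
    a1 <- pmin(L, room)
    full <- a1 == L
    ids <- sprintf("r%07d", rid + seq_len(n_reads))
    seg <- list(data.table::data.table(
      read_id = ids[full], ref_start = bstart[bi[full]] + off[full],
      ref_end = bstart[bi[full]] + off[full] + L,
      left_unaligned = 0L, right_unaligned = 0L))
    # junction-spanning reads: a local aligner reports both segments (split
    # read); each segment carries the rest of the read as a soft clip.
    # Segments shorter than the aligner sensitivity floor are not reported.
    min_seg <- 40L
    for (i in which(!full)) {
      left_len <- a1[i]
      if (left_len >= min_seg)
        seg[[length(seg) + 1L]] <- data.table::data.table(
          read_id = ids[i], ref_start = bstart[bi[i]] + off[i],
          ref_end = bend[bi[i]], left_unaligned = 0L,
          right_unaligned = L - left_len)
      if (bi[i] < length(blen)) {
        nb <- bi[i] + 1L
        a2 <- min(L - left_len, blen[nb])
        if (a2 >= min_seg)
          seg[[length(seg) + 1L]] <- data.table::data.table(
            read_id = ids[i], ref_start = bstart[nb], ref_end = bstart[nb] + a2,
            left_unaligned = left_len, right_unaligned = L - left_len - a2)
      }
    }
    segs <- data.table::rbindlist(seg)
    alen <- segs$ref_end - segs$ref_start
    nerr <- if (config$reads$error_rate > 0)
      rbinom(nrow(segs), alen, config$reads$error_rate) else integer(nrow(segs))
    segs[, `:=`(chrom = cn, query_length = L,
                identity_pct = 100 * (alen - nerr) / alen, unique_aln = TRUE)]
    data.table::setcolorder(segs, c("read_id", "chrom", "ref_start", "ref_end",
                                    "query_length", "left_unaligned",
                                    "right_unaligned", "identity_pct",
                                    "unique_aln"))
    out[[cn]] <- segs
    rid <- rid + n_reads
  }
  data.table::rbindlist(out)
}

# Genes placed with controlled TSS-to-TE distances; expression log-normal
# with mean multiplied by suppression_factor when the TSS lies within
# suppression_dist_bp upstream of a spreading-family TE.
simulate_genes <- function(repeats, fams, chrom_lengths, config) {
  g <- config$genes
  n <- g$n_genes
  n_near <- as.integer(round(n * g$near_fraction))
  glen <- g$gene_length_bp
  rgr <- to_granges(repeats)
  candidates <- function(k, near) {
    strand <- sample(c("+", "-"), k, replace = TRUE)
    if (near) {
      ri <- sample.int(nrow(repeats), k, replace = TRUE)
      d <- as.integer(floor(runif(k) * g$max_tss_distance_bp)) + 1L
      tss <- ifelse(strand == "+", repeats$end[ri] + d, repeats$start[ri] - d)
      cn <- repeats$chrom[ri]
    } else {
      ci <- sample.int(length(chrom_lengths), k, replace = TRUE,
                       prob = as.numeric(chrom_lengths))
      cn <- names(chrom_lengths)[ci]
      tss <- as.integer(floor(runif(k) * (chrom_lengths[cn] - glen)))
    }
    dt <- data.table::data.table(
      chrom = cn, start = as.integer(ifelse(strand == "+", tss, tss - glen)),
      strand = strand)
    dt[, end := start + glen]
    dt <- dt[start >= 0 & end <= chrom_lengths[chrom]]
    if (nrow(dt) == 0L) return(dt)
    bgr <- to_granges(dt)
    dt <- dt[GenomicRanges::countOverlaps(bgr, rgr) == 0L]
    if (!near && nrow(dt) > 0L) {
      # demand > max cutoff distance from any repeat (clean "no TE" genes)
      dd <- GenomicRanges::distanceToNearest(to_granges(dt), rgr)
      far_ok <- rep(TRUE, nrow(dt))
      far_ok[S4Vectors::queryHits(dd)] <-
        S4Vectors::mcols(dd)$distance > g$max_tss_distance_bp
      dt <- dt[far_ok]
    }
    dt
  }
  place_n <- function(k, near) {
    acc <- list(); got <- 0L
    for (round in 1:60) {
      if (got >= k) break
      cand <- candidates(2L * (k - got) + 10L, near)
      if (nrow(cand) > 0L) {
        acc[[length(acc) + 1L]] <- utils::head(cand, k - got)
        got <- got + nrow(acc[[length(acc)]])
      }
    }
    data.table::rbindlist(acc)
  }
  genes <- rbind(place_n(n_near, TRUE), place_n(n - n_near, FALSE))
  genes[, gene_id := sprintf("gene%05d", .I)]
  genes[, `:=`(start = as.integer(start), end = as.integer(end))]
  # two exons split by a small intron
  intron <- 200L
  half <- as.integer((glen - intron) / 2)
  exons <- data.table::rbindlist(list(
    genes[, .(gene_id, chrom, start = start, end = start + half)],
    genes[, .(gene_id, chrom, start = end - half, end = end)]))
  genes[, exon_length_bp := 2L * half]
  # suppression truth from realized geometry
  prox <- nearest_upstream_te(genes, repeats,
                              cutoffs = g$suppression_dist_bp)
  spread_fams <- fams[true_class != "non_spreading", family_id]
  genes[, suppressed := prox$nearest_family %in% spread_fams &
          !is.na(prox$distance_bp) &
          prox$distance_bp <= g$suppression_dist_bp]
  near_any <- !is.na(prox$distance_bp) &
    prox$distance_bp <= g$suppression_dist_bp
  psil <- ifelse(near_any & genes$suppressed, g$silent_prob_near, g$silent_prob_far)
  genes[, silent := runif(.N) < psil]
  target <- rlnorm(nrow(genes), meanlog = log(g$mean_rpkm), sdlog = g$sdlog)
  target <- target * ifelse(genes$suppressed, g$suppression_factor, 1)
  target[genes$silent] <- 0
  counts <- data.table::data.table(
    gene_id = genes$gene_id, sample_id = g$sample_id,
    count = rpois(nrow(genes), target * genes$exon_length_bp *
                    g$library_size / 1e9))
  libsizes <- data.table::data.table(sample_id = g$sample_id,
                                     library_size = g$library_size)
  list(genes = genes, exons = exons, counts = counts, libsizes = libsizes)
}

#' Write a simulated bundle to a directory of standard-format files
#'
#' Emits genome.fa, repeats.bed, probes.tsv, signals.tsv, cx_report.tsv,
#' aln.tsv (plus hap2.sam when `sam = TRUE`), genes.gff3, counts.tsv,
#' libsizes.tsv, smallrna.bed, attributes.tsv and truth.json, skipping
#' components the bundle does not carry.
#'
#' @param bundle result of [simulate_bundle()]
#' @param dir output directory (created if needed)
#' @param sam also write alignments as SAM
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir, sam = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  if (!is.null(bundle$genome))
    Biostrings::writeXStringSet(bundle$genome, fp("genome.fa"))
  write_repeats(bundle$repeats, fp("repeats.bed"))
  write_tsv(bundle$probes[, .(probe_id, chrom, start, end,
                              single_copy = as.integer(single_copy))],
            fp("probes.tsv"))
  if (!is.null(bundle$signals)) write_tsv(bundle$signals, fp("signals.tsv"))
  if (!is.null(bundle$cytosines))
    write_cytosine_report(bundle$cytosines, fp("cx_report.tsv"))
  if (!is.null(bundle$alignments)) {
    write_alignments_tsv(bundle$alignments, fp("aln.tsv"))
    if (sam) write_sam(bundle$alignments, bundle$chrom_lengths, fp("hap2.sam"))
  }
  if (!is.null(bundle$genes))
    write_genes_gff3(bundle$genes, bundle$exons, fp("genes.gff3"))
  if (!is.null(bundle$counts)) {
    write_tsv(bundle$counts, fp("counts.tsv"))
    write_tsv(bundle$libsizes, fp("libsizes.tsv"))
  }
  if (!is.null(bundle$smallrna))
    data.table::fwrite(bundle$smallrna, fp("smallrna.bed"), sep = "\t",
                       col.names = FALSE)
  write_tsv(bundle$attributes, fp("attributes.tsv"))
  jsonlite::write_json(bundle$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Compare pipeline outputs against the generator's ground truth
#'
#' @param outputs list with any of: `classes` (family_id, class),
#'   `empty_sites` (from [detect_empty_sites()]), `dm_calls` (differential
#'   calls with `differential` and `direction`), `proximity` + `expression`
#'   (for the suppression-ratio recovery)
#' @param truth the bundle's `truth` element
#' @return list of metrics: `class_accuracy` + `confusion`,
#'   `empty_precision`/`empty_recall`, `frac_higher_with_insertion`,
#'   `expression_ratio` with a 95% CI (delta method on the log ratio)
#' @export
truth_compare <- function(outputs, truth) {
  res <- list()
  if (!is.null(outputs$classes)) {
    tc <- data.table::as.data.table(truth$families)[, .(family_id, true_class)]
    m <- merge(outputs$classes[, .(family_id, class)], tc, by = "family_id")
    if (nrow(m) == 0L) stop("truth_compare: no matching family ids", call. = FALSE)
    res$class_accuracy <- mean(m$class == m$true_class)
    res$confusion <- table(predicted = m$class, truth = m$true_class)
  }
  if (!is.null(outputs$empty_sites)) {
    tcp <- data.table::as.data.table(truth$copies)
    pred <- outputs$empty_sites[status == "empty", repeat_copy_id]
    pos <- tcp[hap2_present == FALSE, copy_id]
    tp <- length(intersect(pred, pos))
    res$empty_precision <- if (length(pred) > 0) tp / length(pred) else NA_real_
    res$empty_recall <- if (length(pos) > 0) tp / length(pos) else NA_real_
  }
  if (!is.null(outputs$dm_calls)) {
    nd <- outputs$dm_calls[differential == TRUE]
    res$n_differential <- nrow(nd)
    res$frac_higher_with_insertion <- if (nrow(nd) > 0)
      mean(nd$direction == "higher_with_insertion") else NA_real_
  }
  if (!is.null(outputs$proximity) && !is.null(outputs$expression) &&
      !is.null(outputs$classes)) {
    x <- merge(outputs$proximity, outputs$expression, by = "gene_id")
    x <- merge(x, outputs$classes[, .(family_id, class)],
               by.x = "nearest_family", by.y = "family_id", all.x = TRUE)
    d0 <- truth$params$suppression_dist_bp %||% 500L
    a <- x[!is.na(distance_bp) & distance_bp <= d0 &
             class %in% c("spreading_both", "spreading_H3K9"), rpkm]
    b <- x[!is.na(distance_bp) & distance_bp <= d0 &
             class == "non_spreading", rpkm]
    if (length(a) >= 2L && length(b) >= 2L) {
      r <- mean(a) / mean(b)
      se2 <- var(a) / (length(a) * mean(a)^2) + var(b) / (length(b) * mean(b)^2)
      res$expression_ratio <- r
      res$expression_ratio_ci <- r * exp(c(-1, 1) * 1.96 * sqrt(se2))
    }
  }
  res
}
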