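# Empty-site read-evidence clauses, detection rule composition, nearest
# probe, and the differential methylation test against the t.test oracle.

ref_repeat <- function() {
  data.table::data.table(chrom = "chr1", start = 10000L, end = 13000L,
                         strand = ".", family_id = "famA",
                         superfamily = "RLG", copy_id = "c1")
}

# a canonical supporting read at the 5' boundary: 80 bp aligned ending at
# the repeat start, 35 bp junction-side overhang, 5 bp opposite tail
base_aln <- function(ref_end = 10000L, aligned = 80L, overhang = 35L,
                     tail = 5L, identity = 96) {
  data.table::data.table(
    read_id = "r1", chrom = "chr1",
    ref_start = ref_end - aligned, ref_end = ref_end,
    query_length = tail + aligned + overhang,
    left_unaligned = tail, right_unaligned = overhang,
    identity_pct = identity, unique_aln = TRUE)
}

test_that("supporting_read: each clause is independently falsifiable", {
  rp <- ref_repeat()
  expect_true(supporting_read(base_aln(), rp, "5prime"))
  # identity threshold is >= 94 exactly
  expect_true(supporting_read(base_aln(identity = 94), rp, "5prime"))
  expect_false(supporting_read(base_aln(identity = 93.5), rp, "5prime"))
  # aligned-outside threshold is > 50
  expect_false(supporting_read(base_aln(aligned = 50L), rp, "5prime"))
  expect_true(supporting_read(base_aln(aligned = 51L), rp, "5prime"))
  # overhang must exceed 20
  expect_false(supporting_read(base_aln(overhang = 20L), rp, "5prime"))
  expect_true(supporting_read(base_aln(overhang = 21L), rp, "5prime"))
  # opposite tail at most 20
  expect_true(supporting_read(base_aln(tail = 20L), rp, "5prime"))
  expect_false(supporting_read(base_aln(tail = 21L), rp, "5prime"))
  # overhang anchored within +/- 3 bp of the boundary
  expect_true(supporting_read(base_aln(ref_end = 10003L), rp, "5prime"))
  expect_false(supporting_read(base_aln(ref_end = 10004L), rp, "5prime"))
  expect_true(supporting_read(base_aln(ref_end = 9997L), rp, "5prime"))
  expect_false(supporting_read(base_aln(ref_end = 9996L), rp, "5prime"))
  # wrong chromosome is FALSE, not an error
  a <- base_aln(); a$chrom <- "chr2"
  expect_false(supporting_read(a, rp, "5prime"))
  # mirrored 3' boundary
  a3 <- data.table::data.table(
    read_id = "r2", chrom = "chr1", ref_start = 13000L, ref_end = 13080L,
    query_length = 120L, left_unaligned = 35L, right_unaligned = 5L,
    identity_pct = 96, unique_aln = TRUE)
  expect_true(supporting_read(a3, rp, "3prime"))
  expect_false(supporting_read(a3, rp, "5prime"))
})

test_that("junction_covered needs > tolerance aligned bases on both sides", {
  rp <- ref_repeat()
  span <- function(s, e) data.table::data.table(
    read_id = "r", chrom = "chr1", ref_start = s, ref_end = e,
    query_length = e - s, left_unaligned = 0L, right_unaligned = 0L,
    identity_pct = 100, unique_aln = TRUE)
  expect_true(junction_covered(span(9960L, 10040L), rp, "5prime"))
  # ends 2 bp inside the repeat: within tolerance -> not covered
  expect_false(junction_covered(span(9960L, 10002L), rp, "5prime"))
  expect_true(junction_covered(span(9960L, 10004L), rp, "5prime"))
  # entirely in the flank
  expect_false(junction_covered(span(9800L, 9990L), rp, "5prime"))
})

test_that("detect_empty_sites composes counts into site status", {
  rp <- ref_repeat()
  sup <- function(k) data.table::rbindlist(lapply(seq_len(k), function(i) {
    a <- base_aln(); a$read_id <- sprintf("s%d", i); a
  }))
  jun <- data.table::data.table(
    read_id = "j1", chrom = "chr1", ref_start = 9950L, ref_end = 10050L,
    query_length = 100L, left_unaligned = 0L, right_unaligned = 0L,
    identity_pct = 100, unique_aln = TRUE)
  expect_equal(detect_empty_sites(sup(3L), rp)$status, "empty")
  expect_equal(detect_empty_sites(sup(2L), rp)$status, "ambiguous")
  # conflicting evidence (supports and a junction read) is never empty
  both <- rbind(sup(5L), jun)
  expect_equal(detect_empty_sites(both, rp)$status, "ambiguous")
  expect_equal(detect_empty_sites(jun, rp)$status, "occupied")
  # non-unique alignments are ignored
  s <- sup(3L); s$unique_aln <- FALSE
  expect_equal(detect_empty_sites(s, rp)$status, "ambiguous")
  # requiring both flanks demands support at each boundary
  expect_equal(detect_empty_sites(sup(6L), rp,
                                  require_both_flanks = TRUE)$status,
               "ambiguous")
})

test_that("reads from a haplotype carrying the TE yield no empty call", {
  set.seed(33)
  b <- small_bundle(seed = 33L, emit = "reads", polymorphism_rate = 0)
  es <- detect_empty_sites(b$alignments, b$repeats)
  expect_equal(sum(es$status == "empty"), 0L)
  expect_gt(sum(es$status == "occupied"), 0L)
})

test_that("nearest_probe: minimal distance, probe_id tie-break, cap", {
  probes <- data.table::data.table(
    probe_id = c("pB", "pA", "pC"), chrom = "chr1",
    start = c(95L, 455L, 8975L), end = c(145L, 505L, 9025L),
    single_copy = TRUE)
  sites <- data.table::data.table(chrom = "chr1", pos = c(0L, 300L, 15000L),
                                  site = c("s1", "s2", "s3"))
  suppressMessages(np <- nearest_probe(sites, probes, cap_bp = 5000L))
  expect_equal(np[site == "s1", probe_id], "pB")    # 120 vs 480
  expect_equal(np[site == "s2", probe_id], "pA")    # equidistant (180): id order
  expect_false("s3" %in% np$site)                   # nearest 6000 bp away
})

test_that("welch_t matches stats::t.test to 1e-10 and drives the call", {
  set.seed(44)
  for (i in 1:25) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), sd = runif(1, .5, 2))
    got <- welch_t(x, y)
    ref <- stats::t.test(x, y)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(welch_t(1, 1:3), ">= 2")
})

test_that("test_differential calls direction only when significant", {
  sig <- data.table::rbindlist(list(
    data.table::data.table(probe_id = "p1", mark = "5mC", genotype = "B73",
                           tissue = "leaf", replicate = 1:3,
                           log_ratio = c(2.0, 2.1, 1.9)),
    data.table::data.table(probe_id = "p1", mark = "5mC", genotype = "Mo17",
                           tissue = "leaf", replicate = 1:3,
                           log_ratio = c(0.0, 0.1, -0.1))))
  d <- test_differential(sig, "p1", "B73", "Mo17")
  expect_true(d$differential)
  expect_lt(d$p_value, 0.01)
  expect_equal(d$direction, "higher_with_insertion")
  sig2 <- data.table::copy(sig)[genotype == "B73",
                                log_ratio := c(0.1, 0.0, -0.1)]
  d2 <- test_differential(sig2, "p1", "B73", "Mo17")
  expect_false(d2$differential)
  expect_true(is.na(d2$direction))
  expect_error(test_differential(sig[replicate == 1 | genotype == "Mo17"],
                                 "p1", "B73", "Mo17"), "replicates")
})
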