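# Context calling, weighted percent methylation, low-copy flank eligibility
# and group comparisons.

test_that("call_context matches the definitions on crafted sequence", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTCCGACATA"))
  #                        0-based pos: 0123456789..
  expect_equal(call_context(g, "chr1", 1L, "+"), "CG")   # CGT
  expect_equal(call_context(g, "chr1", 4L, "+"), "CHG")  # CCG, H = C
  expect_equal(call_context(g, "chr1", 8L, "+"), "CHH")  # CAT
  # minus strand: revcomp evaluation
  expect_equal(call_context(g, "chr1", 2L, "-"), "CG")   # revcomp of CG
  expect_error(call_context(g, "chr1", 0L, "+"), "not a C")
  # read-through runs off the chromosome end -> NA
  g2 <- Biostrings::DNAStringSet(c(chr1 = "ACGTCCGACATC"))
  expect_true(is.na(call_context(g2, "chr1", 11L, "+")))
})

test_that("call_context agrees with the regex oracle on a random genome", {
  set.seed(31)
  seq_fwd <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(c(chrR = seq_fwd))
  chars <- strsplit(seq_fwd, "")[[1]]
  cpos <- which(chars == "C") - 1L
  gpos <- which(chars == "G") - 1L
  pos <- c(sample(cpos, 300), sample(gpos, 300))
  strand <- rep(c("+", "-"), each = 300)
  got <- call_context(g, rep("chrR", 600), pos, strand)
  want <- mapply(regex_context, pos0 = pos, strand = strand,
                 MoreArgs = list(seq_fwd = seq_fwd))
  expect_identical(got, unname(want))
})

test_that("weighted percent methylation and split-invariance", {
  cx <- data.table::data.table(
    chrom = "chr1", position = c(10L, 20L, 30L), strand = "+",
    context = c("CG", "CG", "CHG"),
    meth_count = c(3L, 7L, 0L), total_count = c(10L, 10L, 4L))
  reg <- data.table::data.table(chrom = "chr1", start = 0L, end = 100L)
  s <- region_methylation(cx, reg)
  expect_equal(s[context == "CG", pct], 100 * 10 / 20)  # 50.0
  expect_equal(s[context == "CHG", pct], 0.0)
  expect_true(is.na(s[context == "CHH", pct]))          # missing, not 0
  # splitting the region and re-aggregating counts is exact
  reg2 <- data.table::data.table(chrom = "chr1", start = c(0L, 15L, 25L),
                                 end = c(15L, 25L, 100L))
  s2 <- region_methylation(cx, reg2)
  expect_identical(s, s2)
})

test_that("low-copy flanks drop repeat-overlapping and chromosome-edge flanks", {
  rp <- data.table::data.table(
    chrom = "chr1", start = c(5000L, 6500L, 9500L),
    end = c(6000L, 7500L, 9800L), strand = ".",
    family_id = c("A", "B", "C"), superfamily = "RLG",
    copy_id = c("c1", "c2", "c3"))
  cl <- c(chr1 = 10000L)
  fl <- low_copy_flanks(rp, 1000L, cl)
  # c1's 3' flank [6000,7000) overlaps c2 -> dropped; c2's 5' flank likewise
  expect_false(any(fl$copy_id == "c1" & fl$side == "3prime"))
  expect_false(any(fl$copy_id == "c2" & fl$side == "5prime"))
  # c1's 5' flank [4000,5000) is clean
  expect_true(any(fl$copy_id == "c1" & fl$side == "5prime"))
  # c3 ends 200 bp before the chromosome end -> 3' flank dropped
  expect_false(any(fl$copy_id == "c3" & fl$side == "3prime"))
  # isolated repeat mid-chromosome keeps both flanks
  iso <- rp[1][, `:=`(start = 3000L, end = 3500L)]
  expect_equal(nrow(low_copy_flanks(iso, 1000L, cl)), 2L)
})

test_that("family flank/internal methylation recovers generator levels", {
  b <- small_bundle(seed = 21L, emit = c("signals", "bisulfite"))
  cl <- b$chrom_lengths
  fam_i <- b$truth$families[true_class == "non_spreading", family_id][1]
  s <- family_flank_and_internal(b$cytosines, b$repeats, fam_i,
                                 chrom_lengths = cl)
  # internal CG prob 0.9 -> pct near 90
  expect_equal(s$internal[context == "CG", pct], 90, tolerance = 0.05)
  expect_equal(s$internal[context == "CHG", pct], 80, tolerance = 0.08)
  # flank of a spreading family beats the random baseline
  fam_s <- b$truth$families[true_class == "spreading_both", family_id][1]
  ss <- family_flank_and_internal(b$cytosines, b$repeats, fam_s,
                                  chrom_lengths = cl)
  base <- random_region_baseline(b$cytosines, cl, n_regions = 300L,
                                 region_bp = 1000L, seed = 3L)
  expect_gt(ss$flank[context == "CG", pct], base[context == "CG", pct])
  expect_error(family_flank_and_internal(b$cytosines, b$repeats, "nope",
                                         chrom_lengths = cl), "unknown family")
})

test_that("random baseline is seed-reproducible and near the binomial mean", {
  b <- small_bundle(seed = 22L, emit = "bisulfite")
  cl <- b$chrom_lengths
  r1 <- random_region_baseline(b$cytosines, cl, n_regions = 200L, seed = 11L)
  r2 <- random_region_baseline(b$cytosines, cl, n_regions = 200L, seed = 11L)
  expect_identical(r1, r2)
  # genome is mostly background: CHH baseline prob 0.05 -> pct near 5
  expect_equal(r1[context == "CHH", pct], 5, tolerance = 0.2)
})

test_that("compare_groups: rank-sum against exact enumeration; degenerate input", {
  set.seed(41)
  x <- rnorm(6); y <- rnorm(7) + 2
  got <- compare_groups(list(spreading_both = x, non_spreading = y))
  expect_equal(got$p_value, exact_wilcox_p(x, y), tolerance = 1e-12)
  # completely separated groups, 10 vs 10: minimal two-sided exact p
  a <- 1:10; bb <- 101:110
  got2 <- compare_groups(list(spreading_both = bb + 0.5, non_spreading = a + 0.5))
  expect_equal(got2$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(got2$significant)
  # identical groups -> p = 1 (midrank/exact conventions aside)
  got3 <- compare_groups(list(g = c(1, 2, 3, 4.5), non_spreading = c(1, 2, 3, 4.5)))
  expect_gt(got3$p_value, 0.9)
  got4 <- compare_groups(list(g = 1, non_spreading = c(1, 2)))
  expect_true(is.na(got4$p_value))
  expect_error(compare_groups(list(a = 1:3)), "non_spreading")
})

test_that("positional profile windows and flatness under uniform methylation", {
  # window arithmetic: copy at relative midpoint 0.5 with 20 windows -> 11
  rp <- data.table::data.table(chrom = "chr1", start = 4950L, end = 5050L,
                               strand = ".", family_id = "A",
                               superfamily = "RLG", copy_id = "c1")
  cx <- data.table::data.table(chrom = "chr1",
                               position = c(4000L, 5500L), strand = "+",
                               context = "CG", meth_count = 5L,
                               total_count = 10L)
  classes <- data.table::data.table(family_id = "A", class = "spreading_both")
  pp <- positional_profile(cx, rp, classes, c(chr1 = 10000L), n_windows = 20L)
  expect_equal(unique(pp$window), 11L)
  # uniform synthetic methylation -> flat profile (slope CI covers 0)
  b <- small_bundle(seed = 23L, emit = "bisulfite")
  cls <- b$truth$families[, .(family_id, class = true_class)]
  nonspread <- cls[class == "non_spreading"]
  pp2 <- positional_profile(b$cytosines, b$repeats[family_id %in% nonspread$family_id],
                            nonspread, b$chrom_lengths, n_windows = 10L)
  cg <- pp2[context == "CG"]
  fit <- stats::lm(mean_pct ~ window, data = cg)
  ci <- stats::confint(fit)["window", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})
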