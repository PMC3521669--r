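# IO module: format round trips, coordinate-convention conversion at the
# boundary, and rejection diagnostics carrying file + line number.

make_repeats <- function() {
  data.table::data.table(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(999L, 5000L, 100L), end = c(2000L, 7000L, 900L),
    strand = c("+", "-", "."),
    family_id = c("famA", "famA", "famB"),
    superfamily = c("RLG", "RLG", "RLC"),
    copy_id = c("c1", "c2", "c3"))
}

test_that("BED repeats: parse, round trip, rejection diagnostics", {
  rp <- make_repeats()
  f <- withr::local_tempfile(fileext = ".bed")
  write_repeats(rp, f)
  back <- read_repeats(f)
  expect_equal(as.data.frame(back), as.data.frame(rp))

  # spec'd example line
  writeLines("chr1\t999\t2000\tfamA|RLG|c1\t.\t+", f)
  one <- read_repeats(f)
  expect_equal(one$start, 999L)
  expect_equal(one$end, 2000L)
  expect_equal(one$family_id, "famA")
  expect_equal(one$superfamily, "RLG")

  # empty file -> empty list with warning
  writeLines(character(0), f)
  expect_warning(e <- read_repeats(f), "no repeat records")
  expect_equal(nrow(e), 0L)

  # malformed line reported with its line number
  writeLines(c("chr1\t0\t100\tfamA|RLG|c1", "chr1\tnotanumber\t5\tfamA|RLG|c2"), f)
  expect_error(read_repeats(f), "line 2")

  # missing family tag -> record rejected, others kept
  writeLines(c("chr1\t0\t100\t|RLG|c1", "chr1\t200\t300\tfamA|RLG|c2"), f)
  expect_warning(kept <- read_repeats(f), "without a family tag")
  expect_equal(kept$copy_id, "c2")

  # duplicated copy ids are an error
  writeLines(c("chr1\t0\t100\tfamA|RLG|c1", "chr1\t200\t300\tfamA|RLG|c1"), f)
  expect_error(read_repeats(f), "duplicated copy_id")
})

test_that("GFF3 repeats convert 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste0("chr1\ttest\trepeat_region\t1000\t2000\t.\t+\t.\t",
                      "ID=c1;family_id=famA;superfamily=RLG"),
               paste0("chr1\ttest\trepeat_region\t1\t50\t.\t-\t.\t",
                      "ID=c2;family_id=famB;superfamily=RLX")), f)
  rp <- read_repeats(f)
  expect_equal(rp$start, c(0L, 999L))   # start=1 -> 0
  expect_equal(rp$end, c(50L, 2000L))
  expect_equal(rp[start == 999L, superfamily], "RLG")
})

test_that("probe/signal reader joins, validates and keeps signal-less probes", {
  pf <- withr::local_tempfile(fileext = ".tsv")
  sf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tchrom\tstart\tend\tsingle_copy",
               "p1\tchr1\t100\t150\t1",
               "p2\tchr1\t300\t350\t0",
               "p3\tchr1\t500\t550\t1"), pf)
  sig <- c("probe_id\tmark\tgenotype\ttissue\treplicate\tlog_ratio",
           sprintf("p1\t5mC\tB73\tleaf\t%d\t%.2f", 1:3, c(0.5, 0.7, 0.6)))
  writeLines(sig, sf)
  ps <- read_probe_signals(pf, sf)
  expect_equal(nrow(ps$probes), 3L)
  expect_false(ps$probes[probe_id == "p2", single_copy])
  expect_equal(nrow(ps$signals[probe_id == "p1"]), 3L)

  writeLines(c(sig, sig[2]), sf)   # duplicated replicate row
  expect_error(read_probe_signals(pf, sf), "duplicated")
  writeLines(c(sig[1], "pX\t5mC\tB73\tleaf\t1\t0.1"), sf)
  expect_error(read_probe_signals(pf, sf), "pX")
})

test_that("cytosine report verifies context against the genome", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AACGTCCGCATTG"))
  #                                   pos:   0123456789...
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "chrom\tposition\tstrand\tcontext\tmeth_count\ttotal_count"
  writeLines(c(hdr,
               "chr1\t2\t+\tCG\t3\t10",     # CGT -> CG
               "chr1\t5\t+\tCHG\t1\t8",     # CCG, H = C -> CHG
               "chr1\t8\t+\tCHH\t0\t5",     # CAT -> CHH
               "chr1\t12\t-\tCHH\t2\t6"), f) # - strand: G at 12, left bases TT

  cx <- read_cytosine_report(f, genome)
  expect_equal(cx$context, c("CG", "CHG", "CHH", "CHH"))

  writeLines(c(hdr, "chr1\t2\t+\tCHH\t3\t10"), f)  # wrong context vs genome
  expect_error(read_cytosine_report(f, genome), "mismatch.*chr1:2")
  writeLines(c(hdr, "chr1\t2\t+\tCG\t5\t4"), f)    # meth > total
  expect_error(read_cytosine_report(f, genome), "meth_count")
  writeLines(c(hdr, "chr1\t3\t+\tCG\t1\t4"), f)    # not a C on + strand
  expect_error(read_cytosine_report(f, genome), "not a C")
})

test_that("SAM alignments: NM identity, clips, unique filtering", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:chr1\tLN:10000",
               paste("r1", 0, "chr1", 101, 60, "100M", "*", 0, 0,
                     strrep("A", 100), "*", "NM:i:3", sep = "\t"),
               paste("r2", 0, "chr1", 201, 60, "30S70M", "*", 0, 0,
                     strrep("A", 100), "*", "NM:i:0", sep = "\t"),
               paste("r3", 256, "chr1", 301, 60, "50M", "*", 0, 0,
                     strrep("A", 50), "*", "NM:i:0", sep = "\t")), f)
  aln <- read_alignments(f, format = "sam", unique_only = FALSE)
  r1 <- aln[read_id == "r1"]
  expect_equal(r1$identity_pct, 97.0)            # (100 - 3) / 100
  expect_equal(r1$ref_start, 100L)
  r2 <- aln[read_id == "r2"]
  expect_equal(r2$left_unaligned, 30L)
  expect_equal(r2$ref_end - r2$ref_start, 70L)   # aligned reference span
  expect_false(aln[read_id == "r3", unique_aln]) # secondary flagged
  expect_equal(read_alignments(f, format = "sam", unique_only = TRUE)$read_id,
               c("r1", "r2"))
})

test_that("alignment TSV and SAM writers round-trip", {
  a <- data.table::data.table(
    read_id = c("r1", "r2"), chrom = "chr1",
    ref_start = c(100L, 900L), ref_end = c(400L, 1000L),
    query_length = c(400L, 150L),
    left_unaligned = c(0L, 30L), right_unaligned = c(100L, 20L),
    identity_pct = c(100, 96), unique_aln = c(TRUE, TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alignments_tsv(a, f)
  expect_equal(as.data.frame(read_alignments(f, format = "tsv")),
               as.data.frame(a))
  fs <- withr::local_tempfile(fileext = ".sam")
  write_sam(a, c(chr1 = 10000L), fs)
  back <- read_alignments(fs, format = "sam")
  expect_equal(back$ref_start, a$ref_start)
  expect_equal(back$ref_end, a$ref_end)
  expect_equal(back$left_unaligned, a$left_unaligned)
  expect_equal(back$right_unaligned, a$right_unaligned)
  expect_equal(back$identity_pct, a$identity_pct, tolerance = 0.5)
})

test_that("gene GFF3 writer/reader round-trips with merged exon lengths", {
  genes <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(1000L, 5000L), end = c(3000L, 7000L), strand = c("+", "-"),
    exon_length_bp = c(1800L, 1800L))
  exons <- data.table::data.table(
    gene_id = rep(c("g1", "g2"), each = 2), chrom = "chr1",
    start = c(1000L, 2100L, 5000L, 6100L), end = c(1900L, 3000L, 5900L, 7000L))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_genes_gff3(genes, exons, f)
  back <- read_genes_gff3(f)
  expect_equal(as.data.frame(back$genes[order(gene_id)]),
               as.data.frame(genes[order(gene_id)]))
})
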