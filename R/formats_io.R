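# Readers/writers for the external formats shared by every stage.
#
# Internal coordinate convention: 0-based, half-open [start, end) everywhere
# (BED native). GFF3 (1-based inclusive) is converted at the boundary on read
# and on write. Probe/signal/cytosine/alignment tables are TSV: tab separated,
# header row, "." for missing.

SUPERFAMILIES <- c("RLC", "RLG", "RLX", "LINE")

normalize_superfamily <- function(x) {
  x <- toupper(trimws(x))
  ifelse(x %in% SUPERFAMILIES, x, "other")
}

#' Read a repeat/TE annotation (BED6 or GFF3)
#'
#' BED records carry `family_id|superfamily|copy_id` in the name field;
#' GFF3 records carry `family`/`family_id`, `superfamily` and `ID`/`copy_id`
#' attributes. Records without a family tag are rejected with a warning.
#' Coordinates are normalized to 0-based half-open and records sorted by
#' (chrom, start).
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`
#' @return a `data.table` with columns chrom, start, end, strand, family_id,
#'   superfamily, copy_id
#' @export
read_repeats <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  rep_dt <- if (format == "bed") read_repeats_bed(path) else read_repeats_gff3(path)
  if (nrow(rep_dt) == 0L) {
    warning(sprintf("%s: no repeat records read", path))
    return(rep_dt)
  }
  if (anyDuplicated(rep_dt$copy_id))
    stop(sprintf("%s: duplicated copy_id(s): %s", path,
                 paste(head(unique(rep_dt$copy_id[duplicated(rep_dt$copy_id)]), 5L),
                       collapse = ", ")), call. = FALSE)
  data.table::setorder(rep_dt, chrom, start)
  rep_dt[]
}

read_repeats_bed <- function(path) {
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  family_id = character(), superfamily = character(),
                                  copy_id = character())
  lines <- readLines(path)
  lines_keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(lines_keep)) return(empty)
  lineno <- which(lines_keep)
  fields <- strsplit(lines[lines_keep], "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("%s: line %d: malformed BED record (%d field(s), need >= 4)",
                 path, lineno[which(nf < 4L)[1]], nf[which(nf < 4L)[1]]), call. = FALSE)
  getf <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else ".", "")
  start <- suppressWarnings(as.integer(getf(2)))
  end <- suppressWarnings(as.integer(getf(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0L)
    stop(sprintf("%s: line %d: invalid coordinates '%s %s'", path,
                 lineno[bad[1]], getf(2)[bad[1]], getf(3)[bad[1]]), call. = FALSE)
  name <- strsplit(getf(4), "|", fixed = TRUE)
  family <- vapply(name, function(x) if (length(x) >= 1) x[1] else "", "")
  super <- vapply(name, function(x) if (length(x) >= 2) x[2] else "other", "")
  copy <- vapply(name, function(x) if (length(x) >= 3) x[3] else "", "")
  rej <- !nzchar(family) | family == "."
  if (any(rej))
    warning(sprintf("%s: %d record(s) without a family tag rejected (first at line %d)",
                    path, sum(rej), lineno[which(rej)[1]]))
  dt <- data.table::data.table(
    chrom = getf(1), start = start, end = end,
    strand = ifelse(getf(6) %in% c("+", "-"), getf(6), "."),
    family_id = family, superfamily = normalize_superfamily(super),
    copy_id = copy)[!rej]
  dt[!nzchar(copy_id), copy_id := sprintf("rep%06d", .I)]
  dt
}

read_repeats_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  family <- as.character(mc$family_id %||% mc$family %||% rep(NA_character_, length(gr)))
  super <- as.character(mc$superfamily %||% rep("other", length(gr)))
  copy <- as.character(mc$copy_id %||% mc$ID %||% rep(NA_character_, length(gr)))
  rej <- is.na(family) | !nzchar(family)
  if (any(rej))
    warning(sprintf("%s: %d record(s) without a family attribute rejected", path, sum(rej)))
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,       # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    family_id = family, superfamily = normalize_superfamily(super),
    copy_id = copy)[!rej]
  dt[strand == "*", strand := "."]
  dt[is.na(copy_id) | !nzchar(copy_id), copy_id := sprintf("rep%06d", .I)]
  dt
}

#' Write repeats as BED6 (name = family|superfamily|copy_id)
#' @param repeats repeat table as from [read_repeats()]
#' @param path output path
#' @export
write_repeats <- function(repeats, path) {
  check_cols(repeats, c("chrom", "start", "end", "strand", "family_id",
                        "superfamily", "copy_id"), "write_repeats")
  bed <- data.table::data.table(
    chrom = repeats$chrom, start = repeats$start, end = repeats$end,
    name = paste(repeats$family_id, repeats$superfamily, repeats$copy_id, sep = "|"),
    score = ".", strand = ifelse(repeats$strand %in% c("+", "-"), repeats$strand, "."))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read probe coordinates and replicate log-ratio signals
#'
#' @param probe_path TSV with columns probe_id, chrom, start, end, single_copy
#' @param signal_path TSV with columns probe_id, mark, genotype, tissue,
#'   replicate, log_ratio
#' @return list with elements `probes` (one row per probe, plus `midpoint`)
#'   and `signals` (long table); probes without signal rows are retained
#' @export
read_probe_signals <- function(probe_path, signal_path) {
  probes <- read_tsv(probe_path)
  check_cols(probes, c("probe_id", "chrom", "start", "end", "single_copy"), probe_path)
  probes[, single_copy := as.logical(as.integer(single_copy))]
  probes[, midpoint := probe_midpoint(start, end)]
  if (anyDuplicated(probes$probe_id))
    stop(sprintf("%s: duplicated probe_id", probe_path), call. = FALSE)
  signals <- read_tsv(signal_path)
  check_cols(signals, c("probe_id", "mark", "genotype", "tissue", "replicate",
                        "log_ratio"), signal_path)
  if (anyDuplicated(signals[, .(probe_id, mark, genotype, tissue, replicate)]))
    stop(sprintf("%s: duplicated (probe_id, mark, genotype, tissue, replicate) row",
                 signal_path), call. = FALSE)
  unknown <- setdiff(signals$probe_id, probes$probe_id)
  if (length(unknown) > 0L)
    stop(sprintf("%s: signal rows reference unknown probe_id(s): %s", signal_path,
                 paste(head(unknown, 10L), collapse = ", ")), call. = FALSE)
  list(probes = probes[], signals = signals[])
}

#' Read a per-cytosine bisulfite report
#'
#' Columns: chrom, position (0-based), strand, context, meth_count,
#' total_count. If a genome is supplied the context is recomputed from the
#' sequence and must agree with the file (the column may also be absent or
#' missing, in which case it is filled).
#'
#' @param path report TSV
#' @param genome optional `DNAStringSet` for context verification
#' @return data.table of cytosine records
#' @export
read_cytosine_report <- function(path, genome = NULL) {
  cx <- read_tsv(path)
  check_cols(cx, c("chrom", "position", "strand", "meth_count", "total_count"), path)
  bad <- cx[meth_count < 0 | meth_count > total_count]
  if (nrow(bad) > 0L)
    stop(sprintf("%s: meth_count > total_count at %s:%d", path,
                 bad$chrom[1], bad$position[1]), call. = FALSE)
  if (!is.null(genome)) {
    called <- call_context(genome, cx$chrom, cx$position, cx$strand)
    if (anyNA(called)) {
      warning(sprintf("%s: %d record(s) with undefined context near chromosome edge skipped",
                      path, sum(is.na(called))))
      cx <- cx[!is.na(called)]
      called <- called[!is.na(called)]
    }
    if ("context" %in% names(cx) && any(!is.na(cx$context))) {
      mm <- which(!is.na(cx$context) & cx$context != called)
      if (length(mm) > 0L)
        stop(sprintf("%s: context mismatch vs genome at %s:%d (file %s, genome %s)",
                     path, cx$chrom[mm[1]], cx$position[mm[1]],
                     cx$context[mm[1]], called[mm[1]]), call. = FALSE)
    }
    cx[, context := called]
  } else if (!"context" %in% names(cx)) {
    stop(sprintf("%s: no context column and no genome supplied", path), call. = FALSE)
  }
  if (!all(cx$context %in% c("CG", "CHG", "CHH")))
    stop(sprintf("%s: invalid context value(s)", path), call. = FALSE)
  cx[]
}

#' @rdname read_cytosine_report
#' @param cx cytosine table
#' @export
write_cytosine_report <- function(cx, path) {
  write_tsv(cx[, .(chrom, position, strand, context, meth_count, total_count)], path)
}

#' Read whole-genome read alignments (SAM or tabular)
#'
#' SAM mode computes percent identity from the NM tag as
#' `100 * (aligned_len - NM) / aligned_len` (aligned_len = M + I + D CIGAR
#' columns; indels count as mismatches) and populates the unaligned tails
#' from soft/hard clips. The TSV fallback carries the columns read_id, chrom,
#' ref_start, ref_end, query_length, left_unaligned, right_unaligned,
#' identity_pct, unique directly.
#'
#' @param path SAM or TSV file
#' @param format `"auto"`, `"sam"` or `"tsv"`
#' @param unique_only drop secondary/supplementary (SAM) or `unique == FALSE`
#'   records
#' @return data.table of alignments (0-based half-open reference span)
#' @export
read_alignments <- function(path, format = c("auto", "sam", "tsv"),
                            unique_only = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  aln <- if (format == "sam") read_alignments_sam(path) else {
    a <- read_tsv(path)
    check_cols(a, c("read_id", "chrom", "ref_start", "ref_end", "query_length",
                    "left_unaligned", "right_unaligned", "identity_pct", "unique"), path)
    data.table::setnames(a, "unique", "unique_aln")
    a[, unique_aln := as.logical(as.integer(unique_aln))]
    a
  }
  if (unique_only) aln <- aln[unique_aln == TRUE]
  aln[]
}

read_alignments_sam <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "qwidth"), tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !is.na(x$pos)
  cig <- parse_cigar(x$cigar[mapped])
  nm <- x$tag$NM[mapped]
  if (anyNA(nm))
    stop(sprintf("%s: NM tag missing for %d record(s); use the TSV alignment fallback",
                 path, sum(is.na(nm))), call. = FALSE)
  flag <- x$flag[mapped]
  identity <- 100 * (cig$aligned_len - nm) / cig$aligned_len
  data.table::data.table(
    read_id = x$qname[mapped],
    chrom = as.character(x$rname[mapped]),
    ref_start = x$pos[mapped] - 1L,
    ref_end = x$pos[mapped] - 1L + cig$ref_span,
    query_length = x$qwidth[mapped] + cig$hard_left + cig$hard_right,
    left_unaligned = cig$clip_left,
    right_unaligned = cig$clip_right,
    identity_pct = identity,
    unique_aln = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L)
}

# CIGAR decomposition for clip/identity bookkeeping (no indel-aware
# realignment: M/=/X consume both, I query, D/N reference).
parse_cigar <- function(cigar) {
  n <- length(cigar)
  out <- list(clip_left = integer(n), clip_right = integer(n),
              hard_left = integer(n), hard_right = integer(n),
              aligned_len = integer(n), ref_span = integer(n))
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", tk))
    op <- substring(tk, nchar(tk))
    k <- length(op)
    lead <- 0L
    while (lead < k && op[lead + 1L] %in% c("S", "H")) lead <- lead + 1L
    trail <- 0L
    while (trail < k - lead && op[k - trail] %in% c("S", "H")) trail <- trail + 1L
    out$clip_left[i] <- sum(len[seq_len(lead)])
    out$clip_right[i] <- if (trail > 0L) sum(len[(k - trail + 1L):k]) else 0L
    out$hard_left[i] <- sum(len[seq_len(lead)][op[seq_len(lead)] == "H"])
    out$hard_right[i] <- if (trail > 0L)
      sum(len[(k - trail + 1L):k][op[(k - trail + 1L):k] == "H"]) else 0L
    mid <- if (k - lead - trail > 0L) (lead + 1L):(k - trail) else integer(0)
    out$aligned_len[i] <- sum(len[mid][op[mid] %in% c("M", "=", "X", "I", "D")])
    out$ref_span[i] <- sum(len[mid][op[mid] %in% c("M", "=", "X", "D", "N")])
  }
  out
}

#' @rdname read_alignments
#' @param aln alignment table (as returned by `read_alignments`)
#' @export
write_alignments_tsv <- function(aln, path) {
  out <- data.table::copy(aln)
  data.table::setnames(out, "unique_aln", "unique")
  out[, unique := as.integer(unique)]
  write_tsv(out, path)
}

#' Write gapless alignments as SAM (lS mM rS records with NM tags)
#'
#' Intended for the synthetic read generator; alignments must be gapless so
#' that the reference span equals the aligned query span.
#'
#' @param aln alignment table
#' @param chrom_lengths named vector of chromosome lengths
#' @param path output SAM path
#' @export
write_sam <- function(aln, chrom_lengths, path) {
  m <- aln$ref_end - aln$ref_start
  qlen <- aln$query_length
  stopifnot(all(aln$left_unaligned + aln$right_unaligned + m == qlen))
  cigar <- paste0(ifelse(aln$left_unaligned > 0, paste0(aln$left_unaligned, "S"), ""),
                  m, "M",
                  ifelse(aln$right_unaligned > 0, paste0(aln$right_unaligned, "S"), ""))
  nm <- as.integer(round(m * (1 - aln$identity_pct / 100)))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), as.integer(chrom_lengths)))
  rec <- paste(aln$read_id,
               ifelse(aln$unique_aln, 0L, 256L),
               aln$chrom, aln$ref_start + 1L, 60L, cigar, "*", 0L, 0L,
               strrep("N", qlen), "*", paste0("NM:i:", nm), sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects `gene` features with `ID` and `exon` features with `Parent`.
#' Exons are merged per gene before computing exon length.
#'
#' @param path GFF3 file
#' @return list with `genes` (gene_id, chrom, start, end, strand,
#'   exon_length_bp) and `exons` (gene_id, chrom, start, end), 0-based
#'   half-open
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  g <- gr[type == "gene"]
  e <- gr[type == "exon"]
  if (length(g) == 0L) stop(sprintf("%s: no gene features", path), call. = FALSE)
  genes <- data.table::data.table(
    gene_id = as.character(g$ID),
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L, end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)))
  parent <- vapply(as.list(e$Parent), function(p) p[1], "")
  exons <- data.table::data.table(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(e)),
    start = GenomicRanges::start(e) - 1L, end = GenomicRanges::end(e))
  # merge overlapping exons within gene
  exons <- exons[, {
    ir <- IRanges::reduce(to_iranges(start, end))
    .(chrom = chrom[1], start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }, by = gene_id]
  el <- exons[, .(exon_length_bp = sum(end - start)), by = gene_id]
  genes <- el[genes, on = "gene_id"]
  if (any(is.na(genes$exon_length_bp) | genes$exon_length_bp <= 0))
    stop(sprintf("%s: gene(s) without exons", path), call. = FALSE)
  data.table::setcolorder(genes, c("gene_id", "chrom", "start", "end", "strand",
                                   "exon_length_bp"))
  list(genes = genes[], exons = exons[])
}

#' @rdname read_genes_gff3
#' @param genes,exons tables as returned by `read_genes_gff3`
#' @export
write_genes_gff3 <- function(genes, exons, path) {
  lines <- "##gff-version 3"
  gl <- sprintf("%s\tteSpread\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                genes$chrom, genes$start + 1L, genes$end, genes$strand, genes$gene_id)
  ex <- exons[genes[, .(gene_id)], on = "gene_id"]
  el <- sprintf("%s\tteSpread\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                ex$chrom, ex$start + 1L, ex$end,
                genes$strand[match(ex$gene_id, genes$gene_id)], ex$gene_id)
  writeLines(c(lines, gl, el), path)
  invisible(path)
}

#' Read per-gene counts and library sizes
#' @param counts_path TSV: gene_id, sample_id, count
#' @param libsize_path TSV: sample_id, library_size
#' @return list with `counts` and `libsizes` data.tables
#' @export
read_counts <- function(counts_path, libsize_path) {
  counts <- read_tsv(counts_path)
  check_cols(counts, c("gene_id", "sample_id", "count"), counts_path)
  libs <- read_tsv(libsize_path)
  check_cols(libs, c("sample_id", "library_size"), libsize_path)
  list(counts = counts[], libsizes = libs[])
}

#' Read small-RNA mapped intervals (BED3+)
#' @param path BED file
#' @return data.table chrom, start, end
#' @export
read_smallrna_bed <- function(path) {
  if (file.size(path) == 0L) {
    warning(sprintf("%s: empty file", path))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  data.table::setnames(dt, 1:3, c("chrom", "start", "end"))
  dt[, .(chrom, start, end)]
}
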