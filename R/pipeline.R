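# End-to-end orchestration: simulate (or load) -> profile -> classify ->
# bisulfite summaries -> empty sites -> expression -> characterization ->
# truth comparison, with a consolidated JSON report. Every stage default
# equals the published threshold where one exists.

#' Default pipeline stage parameters
#'
#' Bin width 200 bp; assignment window 5 kb with 4 kb profiles; 10,000
#' pseudo-insertions; B = 10,000 resamples; alpha = 0.001 over the first 4
#' bins (800 bp); empty-site read criteria (3, 50, 94, 20, 20, 3);
#' differential-methylation alpha 0.01; expression cutoffs
#' 500/1000/2500/5000 bp; 1 kb bisulfite flanks.
#'
#' @return named list of parameters
#' @export
pipeline_params <- function() {
  list(bin_width_bp = 200L, max_distance_bp = 5000L, profile_window_bp = 4000L,
       min_probes = 1000L, n_null = 10000L, B = 10000L, alpha = 0.001,
       required_bins = 4L, empty_site = empty_site_params(), dm_alpha = 0.01,
       cutoffs = c(500L, 1000L, 2500L, 5000L), flank_bp = 1000L,
       n_random_regions = 10000L, seed = 1L)
}

#' Run the full analysis pipeline on a simulated bundle
#'
#' @param bundle a bundle from [simulate_bundle()] (or assembled from files
#'   read by the formats module: the same element names are expected)
#' @param params stage parameters, see [pipeline_params()]; any subset can
#'   be overridden
#' @param out_dir optional directory for stage TSV outputs and report.json
#' @return list: profiles, classes, null seed/params echo, bisulfite
#'   summaries, empty sites + differential calls, expression tables,
#'   characterization tables, truth metrics (when the bundle has truth)
#' @export
run_pipeline <- function(bundle, params = list(), out_dir = NULL) {
  p <- utils::modifyList(pipeline_params(), params)
  gw <- bundle$config$genotype_with %||% "B73"
  gwo <- bundle$config$genotype_without %||% "Mo17"
  res <- list(params = p)

  asg <- assign_probes(bundle$probes, bundle$repeats,
                       max_distance_bp = p$max_distance_bp)
  marks <- intersect(c("5mC", "H3K9me2", "H3K27me3"),
                     unique(bundle$signals$mark))
  res$profiles <- profile_matrix(asg, bundle$signals, marks = marks,
                                 genotype = gw, min_probes = p$min_probes,
                                 profile_window_bp = p$profile_window_bp,
                                 bin_width_bp = p$bin_width_bp)
  null <- generate_null_sites(bundle$probes, bundle$signals, marks = marks,
                              n_sites = p$n_null, seed = p$seed,
                              genotype = gw,
                              profile_window_bp = p$profile_window_bp,
                              bin_width_bp = p$bin_width_bp)
  fam_sizes <- bundle$repeats[, .(n_copies = .N), by = family_id]
  res$classes <- classify_all(res$profiles, null, fam_sizes, alpha = p$alpha,
                              required_bins = p$required_bins, B = p$B,
                              seed = p$seed)
  cls <- res$classes[, .(family_id, class)]

  if (!is.null(bundle$cytosines)) {
    fams <- unique(cls$family_id)
    bs <- lapply(fams, function(f) {
      s <- family_flank_and_internal(bundle$cytosines, bundle$repeats, f,
                                     flank_bp = p$flank_bp,
                                     chrom_lengths = bundle$chrom_lengths)
      rbind(cbind(family_id = f, region_type = "flank", s$flank),
            cbind(family_id = f, region_type = "internal", s$internal))
    })
    bs <- data.table::rbindlist(bs)
    rand <- cbind(family_id = "RANDOM", region_type = "random",
                  random_region_baseline(bundle$cytosines, bundle$chrom_lengths,
                                         n_regions = p$n_random_regions,
                                         region_bp = p$flank_bp, seed = p$seed))
    res$bsmeth <- rbind(bs, rand)
  }

  if (!is.null(bundle$alignments)) {
    es <- detect_empty_sites(bundle$alignments, bundle$repeats,
                             params = p$empty_site)
    es <- merge(es, cls, by = "family_id", all.x = TRUE)
    res$empty_sites <- es
    emp <- es[status == "empty"]
    if (nrow(emp) > 0L && !is.null(bundle$signals)) {
      emp[, pos := ifelse(boundary_tested == "3prime", end, start)]
      np <- nearest_probe(emp, bundle$probes)
      dm <- data.table::rbindlist(lapply(seq_len(nrow(np)), function(i)
        cbind(repeat_copy_id = np$repeat_copy_id[i], class = np$class[i],
              test_differential(bundle$signals, np$probe_id[i], gw, gwo,
                                mark = "5mC", alpha = p$dm_alpha))))
      res$dm_calls <- dm
      res$dm_summary <- summarize_empty_sites(dm, bundle$signals,
                                              bundle$probes, gw, gwo,
                                              alpha = p$dm_alpha)
    }
  }

  if (!is.null(bundle$counts)) {
    expr <- gene_expression(bundle$genes, bundle$counts, bundle$libsizes)
    prox <- nearest_upstream_te(bundle$genes, bundle$repeats,
                                cutoffs = p$cutoffs)
    res$expression <- expr
    res$proximity <- prox
    res$expr_comparison <- stratified_comparison(prox, expr, cls,
                                                 cutoffs = p$cutoffs)
    res$prop_expressed <- proportion_expressed(prox, expr, cls,
                                               cutoffs = p$cutoffs)
  }

  if (!is.null(bundle$attributes)) {
    attr_cls <- merge(bundle$attributes, cls, by = "family_id")
    res$superfamily <- superfamily_composition(cls, bundle$attributes)
    res$chrom_dist <- chromosomal_distribution(bundle$repeats,
                                               bundle$chrom_lengths,
                                               classes = cls)
    if (!is.null(bundle$smallrna))
      res$smallrna <- smallrna_stats(bundle$smallrna, bundle$repeats)
    res$attributes <- attr_cls
  }

  if (!is.null(bundle$truth)) {
    res$truth_metrics <- truth_compare(
      list(classes = cls, empty_sites = res$empty_sites,
           dm_calls = res$dm_calls, proximity = res$proximity,
           expression = res$expression), bundle$truth)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("profiles", "classes", "bsmeth", "empty_sites", "dm_calls",
                 "expr_comparison", "prop_expressed", "superfamily")) {
      if (!is.null(res[[nm]]) && is.data.frame(res[[nm]]))
        write_tsv(res[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
    report <- list(
      params = p[setdiff(names(p), "empty_site")],
      empty_site_params = p$empty_site,
      class_counts = as.list(table(res$classes$class)),
      truth_metrics = lapply(res$truth_metrics, function(x)
        if (inherits(x, "table")) as.data.frame(x) else x))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
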