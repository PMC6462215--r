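#' Run the full synthetic ChIP-nexus analysis pipeline
#'
#' Simulates a genome with planted binding sites and gene models, emits
#' ChIP-nexus reads for every factor/condition combination plus an input
#' control, preprocesses them (trim, barcode, align, mapq filter, dedup),
#' calls peaks against the input, annotates peaks against the gene models,
#' computes two-factor overlap and condition-retention statistics, detects
#' border pairs, builds midpoint-referenced co-positioning distributions
#' and profiles the GRE motif around summits. Deterministic for a fixed
#' `sim$seed`.
#'
#' @param sim A [sim_config()] object (includes the seed).
#' @param config A [pipeline_config()] object.
#' @param outdir Output directory for summary tables, per-stage BED/TSV
#'   files and the run manifest; `NULL` skips all file output.
#' @param cobind_condition Condition used for overlap/border/co-positioning
#'   analyses (the pulse condition by default).
#' @param reference_factor Factor whose peaks anchor the co-positioning
#'   midpoints.
#' @return A list: `genome`, `truth`, `genes`, per-sample `logs`, `peaks`
#'   (per factor/condition), `annotation`, `table1`, `categories`, `venn`,
#'   `retention`, `borders`, `copositioning` (distributions + similarity),
#'   `motif_fractions`, `manifest`.
#' @export
run_pipeline <- function(sim = sim_config(), config = pipeline_config(),
                         outdir = NULL, cobind_condition = "CORT",
                         reference_factor = "GR") {
  conditions <- names(sim$occupancy)
  factors <- names(sim$occupancy[[1]])

  genome0 <- simulate_genome(sim)
  planted <- plant_sites(genome0, sim)
  genome <- planted$genome
  truth <- planted$truth
  genes <- simulate_gene_models(sim)
  chrom_sizes <- stats::setNames(Biostrings::width(genome), names(genome))

  input <- simulate_input_reads(genome, sim)
  input_pp <- preprocess_reads(input$reads, genome, config)
  control_profile <- build_stop_profile(input_pp$tags, chrom_sizes)

  logs <- list(input = input_pp$log)
  peaks <- list(); profiles <- list(); annotation <- list()
  t1 <- list(); cats <- list()
  for (fac in factors) {
    for (cond in conditions) {
      key <- paste0(fac, "_", cond)
      rd <- simulate_nexus_reads(genome, truth, cond, fac, sim)
      pp <- preprocess_reads(rd$reads, genome, config)
      logs[[key]] <- pp$log
      prof <- build_stop_profile(pp$tags, chrom_sizes)
      pk <- call_peaks(prof, control_profile, config)
      ann <- annotate_peaks(pk, genes, config)
      gw <- genes_with_peaks(ann)
      peaks[[key]] <- pk
      profiles[[key]] <- prof
      annotation[[key]] <- ann
      t1[[key]] <- data.frame(
        factor = fac, condition = cond, n_peaks = nrow(pk),
        n_genes_with_peaks = nrow(gw$per_gene),
        genes_single_peak = unname(gw$summary["single"]),
        genes_multiple_peaks = unname(gw$summary["multiple"]))
      tab <- table(factor(ann$category,
                          levels = c("within_gene", "upstream_5kb",
                                     "downstream_5kb", "intergenic")))
      cats[[key]] <- data.frame(factor = fac, condition = cond,
                                category = names(tab),
                                count = as.integer(tab))
    }
  }
  table1 <- do.call(rbind, t1); rownames(table1) <- NULL
  categories <- do.call(rbind, cats); rownames(categories) <- NULL

  # condition-retention ratios relative to the pulse condition
  retention <- do.call(rbind, lapply(factors, function(fac) {
    pulse <- nrow(peaks[[paste0(fac, "_", cobind_condition)]])
    do.call(rbind, lapply(setdiff(conditions, cobind_condition),
                          function(cond) {
      data.frame(factor = fac, condition = cond,
                 ref_condition = cobind_condition,
                 n_peaks = nrow(peaks[[paste0(fac, "_", cond)]]),
                 ref_peaks = pulse,
                 pct_of_ref = if (pulse > 0)
                   count_ratio(nrow(peaks[[paste0(fac, "_", cond)]]), pulse)
                 else NA_real_)
    }))
  }))
  rownames(retention) <- NULL

  # two-factor Venn at the pulse condition
  fa <- factors[1]; fb <- factors[2]
  ov <- overlap_sets(peaks[[paste0(fa, "_", cobind_condition)]],
                     peaks[[paste0(fb, "_", cobind_condition)]])
  venn <- data.frame(condition = cobind_condition, factor_a = fa,
                     factor_b = fb, n_a = ov$n_a, n_b = ov$n_b,
                     n_a_only = ov$n_a_only, n_b_only = ov$n_b_only,
                     n_a_overlapping = ov$n_a_overlapping,
                     n_b_overlapping = ov$n_b_overlapping)

  # border pairs at the pulse condition
  borders <- lapply(stats::setNames(factors, factors), function(fac) {
    key <- paste0(fac, "_", cobind_condition)
    call_border_pairs(profiles[[key]], peaks[[key]], config)
  })

  # midpoint-referenced co-positioning, reference = reference_factor
  other <- setdiff(factors, reference_factor)[1]
  ref_key <- paste0(reference_factor, "_", cobind_condition)
  oth_key <- paste0(other, "_", cobind_condition)
  ref_regions <- if (nrow(borders[[reference_factor]]))
    pairs_as_regions(borders[[reference_factor]]) else peaks[[ref_key]]
  oth_regions <- if (nrow(borders[[other]]))
    pairs_as_regions(borders[[other]]) else peaks[[oth_key]]
  cov <- midpoint_coverage(peaks[[ref_key]], ref_regions, oth_regions,
                           config)
  cop_sim <- if (cov$n_sites > 0 && sum(cov$a$count) > 0 &&
                 sum(cov$b$count) > 0)
    distribution_similarity(cov$a, cov$b)
  else list(jsd = NA_real_, correlation = NA_real_)

  # GRE motif profiling at the pulse condition
  gre <- builtin_pwm("GRE")
  motif_fractions <- do.call(rbind, lapply(factors, function(fac) {
    pk <- peaks[[paste0(fac, "_", cobind_condition)]]
    do.call(rbind, lapply(config$motif_windows, function(w) {
      data.frame(factor = fac, condition = cobind_condition, motif = "GRE",
                 window = w,
                 fraction = motif_enrichment_fraction(pk, genome, gre, w))
    }))
  }))
  rownames(motif_fractions) <- NULL

  manifest <- list(
    tool = paste("nexuspipe", as.character(utils::packageVersion("nexuspipe"))),
    seed = sim$seed,
    sim_config = unclass(sim),
    pipeline_config = unclass(config),
    stage_counts = lapply(logs, as.list)
  )

  res <- list(genome = genome, truth = truth, genes = genes, logs = logs,
              peaks = peaks, profiles = profiles, annotation = annotation,
              table1 = table1, categories = categories, venn = venn,
              retention = retention, borders = borders,
              copositioning = list(coverage = cov, similarity = cop_sim,
                                   reference_factor = reference_factor,
                                   other_factor = other),
              motif_fractions = motif_fractions, manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

#' Write pipeline summary tables, per-stage files and the run manifest
#'
#' @param res Result list from [run_pipeline()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_genome_fasta(res$genome, file.path(outdir, "genome.fa"))
  write_truth(res$truth, file.path(outdir, "truth.tsv"),
              file.path(outdir, "truth.bed"))
  write_gene_bed(res$genes, file.path(outdir, "genes.bed"))
  for (key in names(res$peaks))
    write_narrowpeak(res$peaks[[key]],
                     file.path(outdir, paste0("peaks_", key, ".narrowPeak")))
  wt(res$table1, "table1_peak_counts.tsv")
  wt(res$categories, "peak_categories.tsv")
  wt(res$venn, "venn_counts.tsv")
  wt(res$retention, "retention_ratios.tsv")
  for (fac in names(res$borders))
    wt(res$borders[[fac]], paste0("border_pairs_", fac, ".tsv"))
  cov <- res$copositioning$coverage
  wt(data.frame(offset = cov$a$offset, count_a = cov$a$count,
                count_b = cov$b$count, norm_a = cov$a$norm,
                norm_b = cov$b$norm),
     "copositioning_distributions.tsv")
  wt(res$motif_fractions, "motif_fractions.tsv")
  logdf <- do.call(rbind, lapply(names(res$logs), function(k)
    data.frame(sample = k, stage = names(res$logs[[k]]),
               count = unname(res$logs[[k]])))); rownames(logdf) <- NULL
  wt(logdf, "filter_log.tsv")
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
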