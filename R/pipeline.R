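# End-to-end orchestration: scan -> ingest -> transform -> detect ->
# temporal -> patterns -> enrich, with a fixed output layout and a
# machine-readable run manifest. Deterministic given config + seed.

#' Pipeline configuration
#'
#' Aggregates the input paths and analysis constants: raw-IPD outlier cutoff
#' 50,000; minimum per-site per-sample coverage 20; detection FDR 0.05;
#' temporal FDR thresholds 0.05 and 0.3; enrichment threshold on raw Fisher
#' p of 0.1; 4 pattern clusters.
#'
#' @param genome_fasta Genome FASTA path.
#' @param ipd_table Path(s) to long-format IPD TSVs.
#' @param metadata Sample metadata TSV path.
#' @param out_dir Output directory (created if absent).
#' @param annotations Optional gene annotation TSV/GFF3 path.
#' @param term_map Optional term->gene TSV path.
#' @param outlier_cutoff,min_coverage Ingest filters.
#' @param detection_fdr Detection FDR threshold.
#' @param temporal_fdr Temporal FDR thresholds (both are reported).
#' @param enrichment_alpha Raw-p threshold for term enrichment.
#' @param transform `"default"` (alpha = 0.311, lambda = 0.151),
#'   `"optimize"`, or `list(alpha =, lambda =)`.
#' @param k_clusters Number of pattern clusters.
#' @param upstream_window Site-to-gene upstream window (bp).
#' @param motif,modified_offset,motif_name Motif definition scanned.
#' @param circular Whether the genome is circular.
#' @param seed Integer seed for all resampling.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, ipd_table, metadata, out_dir,
                            annotations = NULL, term_map = NULL,
                            outlier_cutoff = 50000, min_coverage = 20L,
                            detection_fdr = 0.05,
                            temporal_fdr = c(0.05, 0.3),
                            enrichment_alpha = 0.1,
                            transform = "default", k_clusters = 4L,
                            upstream_window = 300L,
                            motif = "GATC", modified_offset = 2L,
                            motif_name = "Dam_GATC", circular = TRUE,
                            seed = 1L) {
  stopifnot(outlier_cutoff > 0, min_coverage >= 1L)
  for (f in c(detection_fdr, temporal_fdr, enrichment_alpha)) {
    if (f <= 0 || f >= 1) stop("thresholds must lie in (0,1)")
  }
  stopifnot(k_clusters >= 1L, upstream_window >= 0L)
  cfg <- list(genome_fasta = genome_fasta, ipd_table = ipd_table,
              metadata = metadata, out_dir = out_dir,
              annotations = annotations, term_map = term_map,
              outlier_cutoff = outlier_cutoff,
              min_coverage = as.integer(min_coverage),
              detection_fdr = detection_fdr, temporal_fdr = temporal_fdr,
              enrichment_alpha = enrichment_alpha, transform = transform,
              k_clusters = as.integer(k_clusters),
              upstream_window = as.integer(upstream_window),
              motif = motif, modified_offset = as.integer(modified_offset),
              motif_name = motif_name, circular = isTRUE(circular),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML config path.
#' @param overrides Named list of keys overriding the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

stage_error <- function(stage, e) {
  stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stage_error(stage, e))
}

#' Run the full methylation-analysis pipeline
#'
#' Stages run in order scan, ingest, transform, detect, temporal, patterns,
#' enrich; each output file carries the generating parameters in the run
#' manifest. Reruns with identical config and inputs are identical given the
#' seed.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  genome <- run_stage("scan", read_genome_fasta(config$genome_fasta,
                                                circular = config$circular))
  sites <- run_stage("scan", scan_motif(genome, config$motif,
                                        config$modified_offset,
                                        config$motif_name))
  run_stage("scan", write_sites_bed(sites, out("sites.bed"), overwrite = TRUE))
  gaps <- run_stage("scan", gap_lengths(sites, genome))

  meta <- run_stage("ingest", read_sample_metadata(config$metadata))
  parsed <- run_stage("ingest", {
    parts <- lapply(config$ipd_table, read_ipd_table, metadata = meta,
                    genome = genome)
    list(records = data.table::rbindlist(lapply(parts, `[[`, "records")),
         rejected = data.table::rbindlist(lapply(parts, `[[`, "rejected")))
  })
  cleaned <- run_stage("ingest", clean_observations(
    parsed$records, outlier_cutoff = config$outlier_cutoff,
    min_coverage = config$min_coverage))
  write_tsv_table(cleaned$report, out("ingest_report.tsv"), overwrite = TRUE)

  params <- run_stage("transform", {
    if (identical(config$transform, "default")) transform_params()
    else if (identical(config$transform, "optimize")) {
      optimize_params(split(cleaned$observations$ipd,
                            cleaned$observations$sample_id))
    } else if (is.list(config$transform)) {
      transform_params(config$transform$alpha, config$transform$lambda)
    } else stop("transform must be 'default', 'optimize' or list(alpha, lambda)")
  })
  write_transform_params(params, out("transform_params.tsv"), overwrite = TRUE)
  # centering offsets over ALL assessed reference positions, motif or not
  offsets <- run_stage("transform", {
    tv <- split(boxcox_transform(cleaned$observations$ipd, params),
                cleaned$observations$sample_id)
    vapply(tv, mean, numeric(1L))
  })

  analysis <- run_stage("ingest", {
    site_key <- paste(sites$position, sites$strand)
    motif_cleaned <- list(
      observations = cleaned$observations[paste(position, strand) %in% site_key],
      cells = cleaned$cells[paste(position, strand) %in% site_key]
    )
    partition_by_site(motif_cleaned, sites)
  })

  detection <- run_stage("detect", detect_methylation(
    analysis, params = params, fdr = config$detection_fdr,
    offsets = offsets, seed = config$seed))
  write_tsv_table(detection$results, out("detection.tsv"), overwrite = TRUE)
  write_tsv_table(detection$summary, out("detection_summary.tsv"),
                  overwrite = TRUE)

  temporal <- run_stage("temporal", temporal_test(analysis, params = params,
                                                  offsets = offsets))
  write_tsv_table(temporal$results, out("temporal.tsv"), overwrite = TRUE)
  selections <- list()
  for (fdr in config$temporal_fdr) {
    sel <- run_stage("temporal", select_significant(temporal$results, fdr))
    selections[[sprintf("fdr_%g", fdr)]] <- sel
    if (nrow(sel)) {
      bed_sites <- data.table::data.table(
        genome_id = genome$id, position = sel$position, strand = sel$strand,
        motif_name = sprintf("%s_q<%g", config$motif_name, fdr))
      write_sites_bed(bed_sites, out(sprintf("significant_fdr%g.bed", fdr)),
                      overwrite = TRUE)
    }
  }

  pattern_fdr <- max(config$temporal_fdr)
  sel <- selections[[sprintf("fdr_%g", pattern_fdr)]]
  patterns <- NULL
  if (!is.null(sel) && nrow(sel) >= max(2L, config$k_clusters)) {
    patterns <- run_stage("patterns", {
      mat <- build_ratio_matrix(analysis, sel, q_threshold = pattern_fdr)
      hc <- ward_cluster(mat)
      assignments <- cut_to_patterns(hc, k = config$k_clusters)
      labels <- label_patterns(assignments, mat)
      write_dendrogram_newick(hc, out("patterns_dendrogram.nwk"),
                              overwrite = TRUE)
      ratios <- data.table::as.data.table(mat, keep.rownames = "site")
      write_tsv_table(merge(labels, ratios, by = "site"),
                      out("patterns.tsv"), overwrite = TRUE)
      list(matrix = mat, hclust = hc, labels = labels)
    })
  } else {
    message("patterns stage skipped: fewer significant sites than clusters")
  }

  enrichment <- NULL
  if (!is.null(config$annotations) && !is.null(config$term_map) &&
      !is.null(sel) && nrow(sel)) {
    enrichment <- run_stage("enrich", {
      ann <- read_annotations(config$annotations)
      tm <- read_term_map(config$term_map)
      mapping <- map_sites_to_genes(sel, ann,
                                    upstream_window = config$upstream_window)
      res <- enrich_terms(mapping$genes, unique(ann$gene_id), tm,
                          alpha = config$enrichment_alpha)
      write_tsv_table(res, out("enrichment.tsv"), overwrite = TRUE)
      list(mapping = mapping, results = res)
    })
  }

  manifest <- list(
    package = "damscan",
    version = as.character(utils::packageVersion("damscan")),
    seed = config$seed,
    transform = list(alpha = params$alpha, lambda = params$lambda),
    thresholds = list(outlier_cutoff = config$outlier_cutoff,
                      min_coverage = config$min_coverage,
                      detection_fdr = config$detection_fdr,
                      temporal_fdr = config$temporal_fdr,
                      enrichment_alpha = config$enrichment_alpha,
                      k_clusters = config$k_clusters,
                      upstream_window = config$upstream_window),
    fdr_scope = "per sample cohort, per method",
    coverage_scope = "per stranded site, per sample",
    n_sites = nrow(sites), n_gaps_gt_1kb = count_long_gaps(gaps, 1000L),
    n_rejected_rows = nrow(parsed$rejected),
    inputs = as.list(tools::md5sum(stats::na.omit(c(
      config$genome_fasta, unlist(config$ipd_table), config$metadata,
      config$annotations, config$term_map))))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(genome = genome, sites = sites, gaps = gaps,
                 params = params, offsets = offsets, analysis = analysis,
                 detection = detection, temporal = temporal,
                 selections = selections, patterns = patterns,
                 enrichment = enrichment, manifest = manifest))
}

#' Prepare an analysis table from raw observation records
#'
#' Convenience wrapper around the ingest/transform steps: applies the
#' outlier and coverage filters, computes per-sample centering offsets over
#' ALL assessed reference positions (motif and non-motif alike — the
#' non-motif background anchors the grand mean), then partitions the motif
#' sites into an analysis table.
#'
#' @param records Long-format observation table (e.g.,
#'   [simulate_timecourse()]`$ipd` or [read_ipd_table()]`$records`).
#' @param sites Motif site table from [scan_motif()].
#' @param params A [transform_params()].
#' @param outlier_cutoff,min_coverage Ingest filters.
#' @return List with `analysis`, `offsets`, `cleaned`, `params`.
#' @export
prepare_analysis <- function(records, sites, params = transform_params(),
                             outlier_cutoff = 50000, min_coverage = 20L) {
  cleaned <- clean_observations(records, outlier_cutoff = outlier_cutoff,
                                min_coverage = min_coverage)
  tv <- split(boxcox_transform(cleaned$observations$ipd, params),
              cleaned$observations$sample_id)
  offsets <- vapply(tv, mean, numeric(1L))
  site_key <- paste(sites$position, sites$strand)
  motif_cleaned <- list(
    observations = cleaned$observations[paste(position, strand) %in% site_key],
    cells = cleaned$cells[paste(position, strand) %in% site_key]
  )
  analysis <- partition_by_site(motif_cleaned, sites)
  list(analysis = analysis, offsets = offsets, cleaned = cleaned,
       params = params)
}

#' Write a simulated dataset bundle to disk
#'
#' Emits the FASTA genome, the long-format IPD TSV, the metadata TSV and the
#' truth ledger the way the pipeline expects them, so a full run needs no
#' external data.
#'
#' @param sim Output of [simulate_timecourse()].
#' @param dir Output directory.
#' @param overwrite Logical.
#' @return Named list of the written paths.
#' @export
write_simulation_bundle <- function(sim, dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome_fasta = file.path(dir, "genome.fasta"),
    ipd_table = file.path(dir, "ipd.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truths = file.path(dir, "truths.tsv")
  )
  write_genome_fasta(sim$genome, paths$genome_fasta, overwrite = overwrite)
  write_tsv_table(sim$ipd, paths$ipd_table, overwrite = overwrite)
  write_tsv_table(sim$metadata, paths$metadata, overwrite = overwrite)
  write_tsv_table(sim$truths, paths$truths, overwrite = overwrite)
  paths
}
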