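#' Pipeline configuration
#'
#' The effective configuration of one end-to-end run: input source
#' (simulate, or read promoters/PWMs/reports from files), report source
#' (the simulated noise channel, or the package's virtual scanner tools),
#' consensus and selection parameters, and the master seed. Fully
#' serializable; [run_pipeline()] writes it next to its outputs.
#'
#' @param simulate generate the dataset with [generate_promoter_set()]
#'   (default TRUE).
#' @param sim_config `simulation_config` used when simulating (default
#'   [study_shape_config()] under `seed`).
#' @param promoters_fasta,promoters_tsv,pwms_path,reports_path input paths
#'   used when `simulate = FALSE` (`reports_path` optional: when absent the
#'   virtual tools are run).
#' @param report_source `"simulate"` (the noise channel applied to planted
#'   truth) or `"scan"` (virtual scanner + enrichment tools on the
#'   sequences).
#' @param scan_thresholds,supportive_thresholds relative-score thresholds
#'   of the virtual main / supportive tools.
#' @param alpha supportive enrichment significance level.
#' @param pseudocount,background scanner regularization and background
#'   base probabilities (`NULL` background: uniform).
#' @param min_main,min_supportive consensus rule (NULL min_main: all main
#'   tools present).
#' @param strict_main error when fewer main reports than `min_main` are
#'   available, instead of relaxing to those present.
#' @param counting_mode `"pooled"` or `"consensus_sites"`.
#' @param tf_top_fraction TF threshold fraction (default 0.40).
#' @param sd_mode `"population"` or `"sample"` gene-total SD.
#' @param module_config optional named vector or YAML path, gene -> module.
#' @param direction_config optional direction annotation (see
#'   [annotate_direction()]).
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim_config = NULL,
                            promoters_fasta = NULL, promoters_tsv = NULL,
                            pwms_path = NULL, reports_path = NULL,
                            report_source = c("simulate", "scan"),
                            scan_thresholds = c(0.75, 0.80, 0.85, 0.90, 0.95),
                            supportive_thresholds = c(0.75, 0.80, 0.85, 0.90),
                            alpha = 0.05, pseudocount = 0.01,
                            background = NULL,
                            min_main = NULL, min_supportive = 1,
                            strict_main = FALSE,
                            counting_mode = c("pooled", "consensus_sites"),
                            tf_top_fraction = 0.40,
                            sd_mode = c("population", "sample"),
                            module_config = NULL, direction_config = NULL,
                            seed = 1) {
  report_source <- match.arg(report_source)
  counting_mode <- match.arg(counting_mode)
  sd_mode <- match.arg(sd_mode)
  if (simulate && is.null(sim_config)) {
    sim_config <- study_shape_config(seed = seed)
  }
  if (!simulate && (is.null(promoters_fasta) || is.null(promoters_tsv) ||
                    is.null(pwms_path))) {
    stop("simulate = FALSE requires promoters_fasta, promoters_tsv and pwms_path")
  }
  structure(
    list(simulate = simulate, sim_config = sim_config,
         promoters_fasta = promoters_fasta, promoters_tsv = promoters_tsv,
         pwms_path = pwms_path, reports_path = reports_path,
         report_source = report_source, scan_thresholds = scan_thresholds,
         supportive_thresholds = supportive_thresholds, alpha = alpha,
         pseudocount = pseudocount, background = background,
         min_main = min_main, min_supportive = min_supportive,
         strict_main = strict_main, counting_mode = counting_mode,
         tf_top_fraction = tf_top_fraction, sd_mode = sd_mode,
         module_config = module_config, direction_config = direction_config,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

## serialize the effective config (sim_config flattened) as YAML
write_effective_config <- function(config, path) {
  ser <- unclass(config)
  if (!is.null(ser$sim_config)) {
    sc <- unclass(ser$sim_config)
    sc$planting_table <- lapply(sc$planting_table, as.list)
    ser$sim_config <- sc
  }
  ser <- ser[!vapply(ser, is.null, logical(1))]
  yaml::write_yaml(ser, path)
  invisible(path)
}

## consensus + selection for one species' reports; returns all stage objects
analyse_species <- function(reports, config, log) {
  mains <- main_reports(reports)
  min_main <- config$min_main
  if (is.null(min_main)) min_main <- length(mains)
  if (length(mains) < min_main) {
    if (config$strict_main) {
      stop("only ", length(mains), " main reports available but min_main = ",
           min_main, " (strict)")
    }
    min_main <- length(mains)
  }
  accepted <- accepted_pairs(reports, min_main, config$min_supportive)
  log("consensus", sprintf("%d accepted (gene, TF) pairs", nrow(accepted)))
  counts <- build_count_matrix(reports, accepted, config$counting_mode,
                               min_main = min_main)
  # discrete site counts (one per cross-tool position cluster): per-gene
  # occurrence semantics, used for the high-affinity classification even
  # when thresholding pools per-tool counts
  site_counts <- if (config$counting_mode == "consensus_sites") {
    counts
  } else {
    build_count_matrix(reports, accepted, "consensus_sites",
                       min_main = min_main)
  }
  th <- compute_gene_threshold(counts, config$sd_mode)
  genes_sel <- select_genes(counts, th)
  log("selection", sprintf(
    "gene mean %.2f (SD %.2f), cutoff %d -> %d genes selected",
    th$gene_mean, th$gene_sd, th$gene_int_cutoff, length(genes_sel)))
  if (length(genes_sel) == 0) {
    return(list(counts = counts, site_counts = site_counts, thresholds = th,
                genes = genes_sel, ranking = NULL, zone = NULL))
  }
  ranking <- rank_tfs(counts, genes_sel)
  tfs_sel <- select_top_tfs(ranking, config$tf_top_fraction)
  log("selection", sprintf("%d candidate TFs -> top %d selected",
                           nrow(ranking), length(tfs_sel)))
  zone <- build_intersection_zone(counts, genes_sel, tfs_sel)
  list(counts = counts, site_counts = site_counts, thresholds = th,
       genes = genes_sel, ranking = ranking, zone = zone)
}

#' Run the whole pipeline and write every artifact
#'
#' Stages, in order: obtain promoters + PWMs (simulated or read), obtain
#' tool reports (noise channel, virtual tools, or read), apply the
#' two-condition consensus and build count matrices per species, compute
#' thresholds and intersection zones per species, intersect the species'
#' TF lists, and classify the human zone TFs. Every artifact lands in
#' `out_dir`, along with the effective config (`config.yaml`) and a
#' deterministic stage log (`log.txt`). Reruns with the same config and
#' seed are byte-identical.
#'
#' @param config a `pipeline_config`.
#' @param out_dir run directory (created; existing files overwritten).
#' @return invisibly, a list with the per-species results, conserved TFs,
#'   classification, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }

  if (config$simulate) {
    sim <- generate_promoter_set(config$sim_config)
    promoters <- sim$promoters
    pwms <- sim$pwms
    truth <- sim$truth
    log("simulate", sprintf("%d promoters, %d planted sites, %d PWMs",
                            length(promoters), nrow(truth), length(pwms)))
    utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    promoters <- read_promoter_set(config$promoters_fasta, config$promoters_tsv)
    pwms <- read_jaspar(config$pwms_path)
    truth <- NULL
    log("load", sprintf("%d promoters, %d PWMs", length(promoters),
                        length(pwms)))
  }
  write_promoter_set(promoters, file.path(out_dir, "promoters.fasta"),
                     file.path(out_dir, "promoters.tsv"))
  write_jaspar(pwms, file.path(out_dir, "pwms.jaspar"))

  species <- vapply(promoters, `[[`, "", "species")
  background <- if (is.null(config$background)) rep(0.25, 4) else config$background

  if (!is.null(config$reports_path)) {
    reports <- read_tool_reports(config$reports_path)
    log("reports", sprintf("read %d tool reports", length(reports)))
  } else if (config$report_source == "simulate") {
    if (is.null(truth)) stop("report_source 'simulate' requires simulated inputs")
    tf_ids <- vapply(pwms, `[[`, "", "tf_id")
    reports <- simulate_tool_reports(promoters, truth, config$sim_config,
                                     tf_ids = tf_ids)
    log("reports", sprintf("simulated %d tool reports", length(reports)))
  } else {
    reports <- list()
    for (sp in unique(species)) {
      prom_sp <- promoters[species == sp]
      reports <- c(reports,
                   virtual_main_reports(prom_sp, pwms, config$scan_thresholds,
                                        background, config$pseudocount, sp),
                   virtual_supportive_reports(prom_sp, pwms,
                                              config$supportive_thresholds,
                                              config$alpha, background,
                                              config$pseudocount, sp))
    }
    log("reports", sprintf("virtual tools produced %d reports",
                           length(reports)))
  }
  write_tool_reports(reports, file.path(out_dir, "tool_reports.tsv"))

  report_species <- vapply(reports, `[[`, "", "species")
  results <- list()
  for (sp in unique(report_species)) {
    res <- analyse_species(reports[report_species == sp], config,
                           function(stage, msg) log(paste0(stage, ":", sp), msg))
    write_count_matrix(res$counts,
                       file.path(out_dir, sprintf("counts_%s.tsv", sp)))
    jsonlite::write_json(
      unclass(res$thresholds),
      file.path(out_dir, sprintf("thresholds_%s.json", sp)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(res$zone)) {
      write_zone(res$zone, res$thresholds,
                 file.path(out_dir, sprintf("zone_%s.tsv", sp)),
                 file.path(out_dir, sprintf("zone_summary_%s.json", sp)))
    }
    results[[sp]] <- res
  }

  conserved <- character()
  if (!is.null(results$human$zone) && !is.null(results$mouse$zone)) {
    conserved <- conserved_tfs(results$human$zone, results$mouse$zone)
    log("crossspecies", sprintf("%d of %d human zone TFs conserved in mouse",
                                length(conserved),
                                length(results$human$zone$tfs)))
  }
  writeLines(conserved, file.path(out_dir, "conserved_tfs.txt"))

  classification <- NULL
  if (!is.null(results$human$zone)) {
    modules <- module_annotation_for(config, promoters, species)
    classification <- classify_tfs(results$human$zone,
                                   results$human$site_counts,
                                   modules, config$direction_config, conserved)
    utils::write.table(classification,
                       file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log("classify", sprintf(
      "%d process-specific, %d pathway-ubiquitous, %d high-affinity TFs",
      sum(classification$scope == "process-specific"),
      sum(classification$scope == "pathway-ubiquitous"),
      sum(classification$high_affinity)))
  }

  write_effective_config(config, file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(results = results, conserved = conserved,
                 classification = classification, reports = reports,
                 truth = truth, out_dir = out_dir))
}

## module annotation: explicit config, else promoter metadata labels
module_annotation_for <- function(config, promoters, species) {
  if (!is.null(config$module_config)) {
    mc <- config$module_config
    if (is.character(mc) && length(mc) == 1 && file.exists(mc)) {
      mc <- unlist(yaml::read_yaml(mc))
    }
    return(mc)
  }
  hum <- promoters[species == "human"]
  stats::setNames(vapply(hum, `[[`, "", "module_label"),
                  vapply(hum, `[[`, "", "gene_id"))
}
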