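#' Pipeline configuration
#'
#' Gathers every tunable of the full analysis with the field-standard
#' defaults: scale-free target R2 0.9, minModuleSize 30, mergeCutHeight
#' 0.25, deepSplit 2, module selection cut 0.5 (trait and MM-GS), lfdr
#' threshold 0.05, switch |r| threshold 0.5, eigen-molecule cut 0.6, DE
#' alpha 0.05.
#'
#' @param expression_path,phenotype_path input TSVs (may be NULL when a
#'   dataset object is passed to [run_pipeline()] directly).
#' @param outdir output directory.
#' @param cor_method `"pearson"` or `"bicor"`.
#' @param signed signed network (default FALSE, unsigned).
#' @param powers,target_R2 soft-threshold candidates and target.
#' @param minModuleSize,mergeCutHeight,deepSplit tree-cut parameters.
#' @param trait_cut,mmgs_cut module-selection thresholds.
#' @param lfdr_cut,switch_threshold,eigen_cutoff,de_alpha downstream
#'   thresholds.
#' @param max_missing_frac QC missingness threshold.
#' @param outlier_z_cut automatic sample-outlier threshold (NULL disables).
#' @param exclude_sample_ids manual exclusion list.
#' @param run_survival run the cutoff scan when survival data is present.
#' @param seed integer seed consumed by any stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression_path = NULL, phenotype_path = NULL,
                            outdir = "dcnet_out",
                            cor_method = "pearson", signed = FALSE,
                            powers = 1:20, target_R2 = 0.9,
                            minModuleSize = 30, mergeCutHeight = 0.25,
                            deepSplit = 2,
                            trait_cut = 0.5, mmgs_cut = 0.5,
                            lfdr_cut = 0.05, switch_threshold = 0.5,
                            eigen_cutoff = 0.6, de_alpha = 0.05,
                            max_missing_frac = 0.5, outlier_z_cut = -2.5,
                            exclude_sample_ids = character(0),
                            run_survival = TRUE, seed = 1) {
  stopifnot(target_R2 > 0, target_R2 <= 1,
            minModuleSize >= 2, mergeCutHeight >= 0, mergeCutHeight < 1,
            deepSplit %in% 0:3,
            trait_cut >= 0, trait_cut <= 1, mmgs_cut >= 0, mmgs_cut <= 1,
            lfdr_cut > 0, lfdr_cut <= 1,
            switch_threshold >= 0, switch_threshold < 1,
            eigen_cutoff > 0, eigen_cutoff <= 2,
            de_alpha > 0, de_alpha <= 1,
            max_missing_frac >= 0, max_missing_frac <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full differential-correlation network pipeline
#'
#' Stages, in order: QC (bad genes/samples, outlier and manual sample
#' exclusion), correlation matrix, soft-threshold pick, adjacency, TOM,
#' dendrogram, module cut, eigengenes, module merging, module-trait and
#' MM/GS statistics, module selection, per-selected-module pairwise
#' differential correlation with lfdr, switch-pair detection, DE node
#' direction, network assembly and export (SIF + GraphML + TSV), and —
#' when survival data is attached — the minimum-p cutoff scan for each hub
#' gene. Every table is written under `config$outdir` and checksummed in
#' the run manifest.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional [expression_dataset()]; read from the configured
#'   paths when NULL.
#' @return invisibly, a list with all intermediate results plus `manifest`
#'   (written to `manifest.json`).
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log,
                         paste0("[", name, "] warning: ",
                                conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  files <- character(0)

  ds <- dataset %||% stage("read", read_expression(config$expression_path,
                                                   config$phenotype_path))

  qc <- stage("qc", good_samples_genes(ds, config$max_missing_frac))
  ds <- qc$dataset
  files <- c(files, write_tsv(qc$report, file.path(config$outdir,
                                                   "qc_report.tsv")))
  dropped <- unique(c(
    if (!is.null(config$outlier_z_cut))
      stage("outliers", detect_outlier_samples(ds, config$outlier_z_cut))
    else character(0),
    intersect(config$exclude_sample_ids, ds$sample_ids)))
  if (length(dropped)) {
    note("excluding ", length(dropped), " sample(s): ",
         paste(dropped, collapse = ", "))
    ds <- exclude_samples(ds, dropped)
  }
  trait <- as.integer(ds$condition == "B")
  if (length(unique(trait)) < 2)
    stop("pipeline needs samples from both conditions after QC")

  cm <- stage("correlation", correlation_matrix(ds, config$cor_method))
  sft <- stage("soft_threshold",
               pick_soft_threshold(cm, config$powers, config$target_R2,
                                   config$signed))
  files <- c(files, write_tsv(sft$table,
                              file.path(config$outdir, "soft_threshold.tsv")))
  adj <- adjacency_matrix(cm, sft$power, config$signed)
  tom <- stage("tom", tom_similarity(adj))
  dend <- cluster_genes(tom)
  modules <- stage("cut", cut_modules(dend, config$minModuleSize,
                                      config$deepSplit))
  result <- list(config = config, dataset = ds, soft_threshold = sft,
                 modules = modules)
  if (all(modules == "grey")) {
    note("no module passed the size threshold; stopping after module cut")
    files <- c(files, write_tsv(
      data.frame(gene = names(modules), module = unname(modules)),
      file.path(config$outdir, "modules.tsv")))
    result$manifest <- write_manifest(config, files, warnings_log, t0)
    return(invisible(result))
  }
  mes <- stage("eigengenes", module_eigengenes(ds, modules))
  merged <- stage("merge", merge_close_modules(ds, modules, mes,
                                               config$mergeCutHeight))
  modules <- merged$modules; mes <- merged$eigengenes
  files <- c(files, write_tsv(
    data.frame(gene = names(modules), module = unname(modules)),
    file.path(config$outdir, "modules.tsv")))
  files <- c(files, write_tsv(
    data.frame(sample_id = rownames(mes$eigengenes), mes$eigengenes,
               check.names = FALSE),
    file.path(config$outdir, "eigengenes.tsv")))

  trait_cors <- stage("module_trait", module_trait_correlation(mes, trait))
  gstats <- stage("mm_gs", gene_module_stats(ds, modules, mes, trait))
  selection <- stage("select",
                     select_significant_modules(trait_cors,
                                                mm_gs_correlation(gstats),
                                                config$trait_cut,
                                                config$mmgs_cut))
  files <- c(files, write_tsv(merge(trait_cors, selection[
    c("module", "mmgs_r", "selected")], by = "module"),
    file.path(config$outdir, "module_trait.tsv")))
  files <- c(files, write_tsv(gstats,
                              file.path(config$outdir, "gene_stats.tsv")))
  selected <- selection$module[selection$selected]
  result$modules <- modules
  result$eigengenes <- mes
  result$trait_cors <- trait_cors
  result$gene_stats <- gstats
  result$selection <- selection

  all_records <- list()
  for (m in selected) {
    genes <- names(modules)[modules == m]
    rec <- stage(paste0("diffcorr_", m),
                 pairwise_differential_correlations(ds, genes, module = m))
    rec <- stage(paste0("lfdr_", m), local_fdr(rec))
    all_records[[m]] <- rec
    files <- c(files, write_tsv(
      format_diffcorr_table(rec),
      file.path(config$outdir, paste0("diffcorr_", m, ".tsv"))))
    files <- c(files, write_tsv(
      format_diffcorr_table(top_differential_pairs(rec, 10,
                                                   config$lfdr_cut)),
      file.path(config$outdir, paste0("top_pairs_", m, ".tsv"))))
  }
  records <- if (length(all_records)) do.call(rbind, all_records)
    else NULL
  result$records <- records

  if (is.null(records) || nrow(records) == 0) {
    note("no selected module; exporting empty network")
    network <- build_network(detect_switched_pairs(
      data.frame(molecule_X = character(), molecule_Y = character(),
                 r1 = numeric(), r2 = numeric())))
  } else {
    sig <- records[!is.na(records$lfdr) & records$lfdr < config$lfdr_cut, ]
    switched <- stage("switch",
                      detect_switched_pairs(sig, config$switch_threshold))
    dirs <- stage("de", de_direction(ds, config$de_alpha))
    network <- stage("network", build_network(switched, dirs))
    result$switched <- switched
    result$directions <- dirs
  }
  result$network <- network
  files <- c(files,
             export_network(network, file.path(config$outdir, "network.sif"),
                            "SIF"),
             export_network(network,
                            file.path(config$outdir, "network.graphml"),
                            "GraphML"),
             export_network(network, file.path(config$outdir, "network"),
                            "TSV"))

  if (isTRUE(config$run_survival) && !is.null(ds$survival) &&
      nrow(network$nodes) > 0) {
    scans <- list()
    top <- utils::head(hub_genes(network, 2)$gene, 2)
    for (g in top) {
      idx <- match(ds$survival$sample_id, ds$sample_ids)
      tab <- ds$survival
      tab$expression <- ds$values[g, idx]
      sc <- tryCatch(cutoff_scan(tab), error = function(e) {
        note("cutoff scan skipped for ", g, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(sc)) {
        scans[[g]] <- sc
        files <- c(files, write_tsv(sc$table, file.path(
          config$outdir, paste0("cutoff_scan_", g, ".tsv"))))
      }
    }
    result$cutoff_scans <- scans
  }

  result$manifest <- write_manifest(config, files, warnings_log, t0)
  invisible(result)
}

# Table-1-style column order: molecule_X, molecule_Y, r1, r2, Lfdr, then
# the extra trailing columns.
format_diffcorr_table <- function(rec) {
  out <- rec[, c("molecule_X", "molecule_Y", "r1", "r2", "lfdr", "module",
                 "Z", "p")]
  names(out)[5] <- "Lfdr"
  out
}

write_manifest <- function(config, files, warnings_log, t0) {
  cfg <- config
  cfg$powers <- paste(range(cfg$powers), collapse = ":")
  manifest <- list(
    config = cfg[setdiff(names(cfg), c("outdir"))],
    outputs = as.list(tools::md5sum(files[file.exists(files)])),
    warnings = warnings_log,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  manifest
}
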