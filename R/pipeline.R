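#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: either file inputs
#' (`counts_file` + `sheet_file`, featureCounts-dialect TSV and sample-sheet
#' CSV) or a simulation (`sim`, a [sim_config()]), plus the DEG thresholds
#' and classifier knobs.
#'
#' @param sim a [sim_config()] used when no input files are given; its
#'   `seed` is overridden by `seed` here.
#' @param counts_file,sheet_file optional input paths; both or neither.
#' @param groups ordered group labels (axes + tie priority).
#' @param thresholds a [deg_thresholds()].
#' @param n_top markers per group.
#' @param correlation_scale `"log2norm"` or `"norm"`.
#' @param cutoff_multiplier SD multiplier for confidence cutoffs.
#' @param pseudocount log-transform pseudocount.
#' @param seed integer master seed for the run.
#' @param outdir optional output directory; when set, [run_pipeline()]
#'   writes a JSON report and TSV/CSV tables there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            counts_file = NULL, sheet_file = NULL,
                            groups = c("SCC", "Pap", "Ctrl"),
                            thresholds = deg_thresholds(),
                            n_top = 10L,
                            correlation_scale = "log2norm",
                            cutoff_multiplier = 1,
                            pseudocount = 1,
                            seed = 1L,
                            outdir = NULL) {
  if (xor(is.null(counts_file), is.null(sheet_file)))
    .stopf("counts_file and sheet_file must be given together")
  structure(list(sim = sim, counts_file = counts_file, sheet_file = sheet_file,
                 groups = groups, thresholds = thresholds,
                 n_top = as.integer(n_top),
                 correlation_scale = correlation_scale,
                 cutoff_multiplier = cutoff_multiplier,
                 pseudocount = pseudocount, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Reads (or simulates) counts, fits the [mace_classifier()] end to end and
#' assembles a machine-readable report. Deterministic given the config
#' seed. When `config$outdir` is set, writes `report.json`, the per-sample
#' LOO table, the DE result tables, the marker panel, size factors and PCA
#' scores.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `fit` (the `mace_classifier`), `report`
#'   (the JSON-ready report list) and, for simulated runs, `truth`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$counts_file)) {
    counts <- read_counts_table(config$counts_file)
    sheet <- read_sample_sheet(config$sheet_file)
  } else {
    simcfg <- config$sim
    simcfg$seed <- config$seed
    sim <- simulate_counts(simcfg)
    counts <- sim$counts; sheet <- sim$sheet; truth <- sim$truth
  }
  fit <- mace_classifier(counts, sheet,
                         groups = config$groups,
                         thresholds = config$thresholds,
                         n_top = config$n_top,
                         correlation_scale = config$correlation_scale,
                         cutoff_multiplier = config$cutoff_multiplier,
                         pseudocount = config$pseudocount)
  report <- .pipeline_report(fit, config, truth)
  if (!is.null(config$outdir)) .write_pipeline_outputs(fit, report, config)
  invisible(list(fit = fit, report = report, truth = truth))
}

.pipeline_report <- function(fit, config, truth) {
  rep <- fit$report
  deg_counts <- lapply(fit$de, function(d) {
    degs <- call_degs(d, fit$thresholds)
    list(up_in_first = length(degs$up_in_A), up_in_second = length(degs$up_in_B))
  })
  marker_recovery <- NULL
  if (!is.null(truth)) {
    marker_recovery <- lapply(fit$groups, function(g) {
      planted <- truth$genes$gene_id[truth$genes$role == "marker" &
                                       !is.na(truth$genes$group) &
                                       truth$genes$group == g]
      block <- fit$panel$gene_id[fit$panel$group == g]
      list(n_block = length(block),
           n_planted_in_block = length(intersect(block, planted)))
    })
    names(marker_recovery) <- fit$groups
  }
  list(
    engine = fit$de_engine,
    seed = config$seed,
    groups = as.list(table(factor(fit$sheet$group, fit$groups))),
    n_genes_filtered = fit$n_genes_filtered,
    thresholds = unclass(fit$thresholds),
    n_top = fit$n_top,
    correlation_scale = fit$correlation_scale,
    cutoff_multiplier = fit$cutoff_multiplier,
    batch_corrected = fit$batch_corrected,
    deg_counts = deg_counts,
    n_specific = lapply(fit$specific_sets, length),
    venn = lapply(fit$venn, as.list),
    panel = fit$panel$gene_id,
    marker_recovery = marker_recovery,
    metrics = list(
      confusion = unname(apply(fit$report$confusion, 1L, as.list)),
      sensitivity = as.list(rep$sensitivity),
      specificity = as.list(rep$specificity),
      accuracy = rep$accuracy,
      auc_per_class = as.list(rep$auc$per_class),
      auc_macro = rep$auc$macro,
      n_classified = rep$n))
}

.write_pipeline_outputs <- function(fit, report, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(fit$loo, out("loo_classification.csv"), row.names = FALSE)
  utils::write.table(fit$panel, out("marker_panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(fit$de))
    utils::write.table(fit$de[[nm]], out(paste0("de_", nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(sample_id = names(fit$size_factors),
                              size_factor = unname(fit$size_factors)),
                   out("size_factors.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(fit$pca$scores),
                              fit$pca$scores),
                   out("pca_scores.csv"), row.names = FALSE)
  invisible(config$outdir)
}
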