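# Pipeline orchestration: the driver-detection stage (pathways + multiplex
# layers -> centrality records -> criterion calls -> multiplex driver set ->
# Venn regions) and the per-condition stage (DEA -> driver/DEG intersection
# -> FDR comparison -> per-gene RF AUC -> top-k).  Configurations are plain
# lists, optionally read from YAML; all randomness flows from one seed.

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

resolve_pathways <- function(x) {
  if (inherits(x, "gene_set_collection")) return(x)
  if (is.character(x) && length(x) == 1) return(read_gene_sets(x))
  stopf("'pathways' must be a gene_set_collection or a GMT path")
}

resolve_multiplex <- function(config) {
  if (!is.null(config$multiplex)) {
    stopifnot(inherits(config$multiplex, "multiplex_network"))
    return(config$multiplex)
  }
  if (is.null(config$layers) || length(config$layers) == 0) {
    stopf("no network layers supplied")
  }
  layers <- lapply(names(config$layers), function(ln) {
    path <- config$layers[[ln]]
    if (inherits(path, "network_layer")) return(path)
    if (!file.exists(path)) stopf("missing layer file: %s", path)
    fmt <- if (grepl("\\.sif$", path)) "sif" else "edge_tsv"
    read_network_layer(path, fmt, ln)
  })
  names(layers) <- names(config$layers)
  multiplex_network(layers)
}

#' Run the multiplex driver-detection stage
#'
#' @param config Named list with entries: `pathways` (object or GMT path),
#'   `multiplex` (object) or `layers` (named list of edge files or layer
#'   objects), and optionally `criterion_mode` (`"literal"`),
#'   `aggregation` (`"per_gene"`), `min_layers` (2), `k_mode`
#'   (`"annotated"`), `gene_filter`, `out_dir`.
#' @return List of class `driver_run`: `records`, `calls`, `result`
#'   (a `multiplex_driver_result`), `venn`, `summary`.
#' @export
run_drivers <- function(config) {
  pathways <- resolve_pathways(config$pathways)
  multiplex <- resolve_multiplex(config)
  criterion_mode <- config$criterion_mode %||% "literal"
  aggregation <- config$aggregation %||% "per_gene"
  min_layers <- config$min_layers %||% 2
  k_mode <- config$k_mode %||% "annotated"

  message(sprintf("drivers: %d pathways, %d layer(s)",
                  length(pathways), length(multiplex$layers)))
  records <- build_centrality_records(multiplex, pathways,
                                      gene_filter = config$gene_filter,
                                      k_mode = k_mode)
  calls <- driver_calls(records, criterion_mode)
  result <- multiplex_drivers(calls, min_layers = min_layers,
                              aggregation = aggregation)
  venn <- venn_region_counts(result$per_layer_sets)
  message(sprintf("drivers: %d records, %d passing call(s), %d driver gene(s)",
                  nrow(records), sum(calls$passes), length(result$driver_genes)))

  summary <- list(stage = "drivers",
                  n_pathways = length(pathways),
                  n_layers = length(multiplex$layers),
                  n_records = nrow(records),
                  n_passing_calls = sum(calls$passes),
                  per_layer_counts = lapply(result$per_layer_sets, length),
                  n_driver_genes = length(result$driver_genes),
                  criterion_mode = criterion_mode,
                  aggregation = aggregation,
                  min_layers = min_layers)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_centrality_records(calls, file.path(config$out_dir, "driver_calls.tsv"))
    for (ln in names(result$per_layer_sets)) {
      writeLines(result$per_layer_sets[[ln]],
                 file.path(config$out_dir, sprintf("drivers_%s.txt", ln)))
    }
    writeLines(result$driver_genes,
               file.path(config$out_dir, "driver_genes.txt"))
    write_tsv(venn, file.path(config$out_dir, "venn_regions.tsv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "drivers_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(records = records, calls = calls, result = result,
                 venn = venn, summary = summary),
            class = "driver_run")
}

resolve_drivers <- function(x) {
  if (inherits(x, "multiplex_driver_result")) return(x$driver_genes)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(toupper(readLines(x, warn = FALSE)))
  }
  as.character(x)
}

#' Run the per-condition stage: DEA, driver intersection, AUC ranking
#'
#' @param config Named list with entries: `drivers` (character vector,
#'   `multiplex_driver_result`, or one-gene-per-line file), `counts`
#'   (matrix or TSV path), `labels` (named factor or TSV path), and
#'   optionally `condition_id`, `logfc_thr` (1), `fdr_thr` (0.01),
#'   `n_trees` (500), `n_folds` (10), `top_k` (10), `seed` (1),
#'   `rounding` (`"truncate_int"`), `out_dir`.
#' @return List of class `condition_run`: `deg_table`, `condition`
#'   (a `condition_driver_result`), `fdr_comparison`, `auc_table`,
#'   `top_k`, `summary`.
#' @export
run_condition <- function(config) {
  drivers <- resolve_drivers(config$drivers)
  counts <- if (is.character(config$counts)) read_expression(config$counts)
            else config$counts
  labels <- if (is.character(config$labels)) read_labels(config$labels)
            else config$labels
  bad <- setdiff(names(labels), colnames(counts))
  if (length(bad) == length(labels)) stopf("labels match no matrix sample")
  condition_id <- config$condition_id %||% "condition"
  seed <- config$seed %||% 1

  deg_table <- run_dea(counts, labels,
                       logfc_thr = config$logfc_thr %||% 1,
                       fdr_thr = config$fdr_thr %||% 0.01,
                       condition_id = condition_id)
  message(sprintf("condition '%s': %d DEGs of %d genes tested",
                  condition_id, sum(deg_table$is_deg), nrow(deg_table)))

  condition <- intersect_driver_degs(drivers, deg_table,
                                     rounding = config$rounding %||% "truncate_int")
  message(sprintf("condition '%s': %d driver DEG(s)",
                  condition_id, length(condition$driver_degs)))
  fdr_cmp <- fdr_comparison(deg_table, condition$driver_degs)

  cfg_rf <- rf_config(n_trees = config$n_trees %||% 500,
                      n_folds = config$n_folds %||% 10,
                      seed = seed)
  if (length(condition$driver_degs) > 0) {
    auc_table <- per_gene_auc_table(normalize_counts(counts), labels,
                                    condition$driver_degs, cfg_rf)
    top_k <- rank_top_k(auc_table, k = config$top_k %||% 10)
  } else {
    auc_table <- data.frame(gene = character(0), auc = numeric(0),
                            n_positive = integer(0), n_negative = integer(0),
                            rank = integer(0))
    top_k <- auc_table
  }

  summary <- list(stage = "condition",
                  condition_id = condition_id,
                  n_genes_tested = nrow(deg_table),
                  n_degs = sum(deg_table$is_deg),
                  n_drivers = length(unique(drivers)),
                  n_driver_degs = length(condition$driver_degs),
                  pct_of_network_drivers = condition$pct_of_network_drivers,
                  top_genes = top_k$gene,
                  seed = seed)
  stopifnot(summary$n_driver_degs <= min(summary$n_degs, summary$n_drivers))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_deg_table(deg_table, file.path(config$out_dir, "deg_table.tsv"))
    writeLines(condition$driver_degs,
               file.path(config$out_dir, "driver_degs.txt"))
    write_tsv(fdr_cmp$summary, file.path(config$out_dir, "fdr_comparison.tsv"))
    write_tsv(auc_table, file.path(config$out_dir, "auc_table.tsv"))
    write_tsv(top_k, file.path(config$out_dir, "top_genes.tsv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "condition_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(deg_table = deg_table, condition = condition,
                 fdr_comparison = fdr_cmp, auc_table = auc_table,
                 top_k = top_k, summary = summary),
            class = "condition_run")
}
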