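# Pan-condition stages: intersection of network drivers with per-condition
# DEGs, cross-condition sharing, FDR comparison between all DEGs and driver
# DEGs, and overlap arithmetic against external driver-gene catalogues.

#' Percentage with an explicit rounding convention
#'
#' `100 * numerator / denominator`, then either rounded to one decimal
#' (`"round1"`) or truncated to an integer (`"truncate_int"`).  Both
#' conventions occur in published driver-gene overlap tables, so the mode is
#' explicit.
#'
#' @param numerator,denominator Non-negative integers, `denominator > 0`.
#' @param mode `"round1"` or `"truncate_int"`.
#' @return Numeric percentage.
#' @export
percentage <- function(numerator, denominator, mode = c("round1", "truncate_int")) {
  mode <- match.arg(mode)
  if (denominator <= 0) stopf("denominator must be > 0")
  pct <- 100 * numerator / denominator
  if (mode == "round1") round(pct, 1) else trunc(pct)
}

#' Intersect network drivers with a condition's DEGs
#'
#' The "cancer driver DEGs" of a condition: flagged DEGs that are also
#' multiplex network drivers, with the percentage of the driver set they
#' cover.
#'
#' @param drivers Character vector of network driver genes (or a
#'   `multiplex_driver_result`).
#' @param deg_table A `deg_table` from [select_degs()] / [run_dea()].
#' @param rounding Rounding mode for the percentage, see [percentage()].
#' @return Object of class `condition_driver_result`: list with
#'   `condition_id`, `degs`, `driver_degs`, `pct_of_network_drivers`.
#' @export
intersect_driver_degs <- function(drivers, deg_table,
                                  rounding = c("truncate_int", "round1")) {
  rounding <- match.arg(rounding)
  if (inherits(drivers, "multiplex_driver_result")) drivers <- drivers$driver_genes
  drivers <- unique(as.character(drivers))
  degs <- sort(deg_table$gene[deg_table$is_deg])
  driver_degs <- sort(intersect(degs, drivers))
  if (length(drivers) == 0) {
    warnf("empty driver set; percentage reported as 0")
    pct <- 0
  } else {
    pct <- percentage(length(driver_degs), length(drivers), mode = rounding)
  }
  structure(list(condition_id = attr(deg_table, "condition_id") %||% "condition",
                 degs = degs, driver_degs = driver_degs,
                 pct_of_network_drivers = pct),
            class = "condition_driver_result")
}

#' @export
print.condition_driver_result <- function(x, ...) {
  cat(sprintf("condition '%s': %d DEGs, %d driver DEGs (%s%% of network drivers)\n",
              x$condition_id, length(x$degs), length(x$driver_degs),
              format(x$pct_of_network_drivers)))
  invisible(x)
}

#' Pairwise shared driver-DEG counts across conditions
#'
#' Symmetric matrix whose entry (a, b) counts the driver DEGs shared by
#' conditions a and b; the diagonal holds the per-condition set sizes.
#'
#' @param results List of `condition_driver_result` objects.
#' @return Integer matrix with condition ids as dimnames.
#' @export
shared_driver_matrix <- function(results) {
  if (length(results) == 0) stopf("need >= 1 condition")
  ids <- vapply(results, `[[`, character(1), "condition_id")
  if (anyDuplicated(ids)) stopf("duplicate condition id(s)")
  sets <- lapply(results, `[[`, "driver_degs")
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  m
}

#' Compare FDR distributions of all DEGs versus driver DEGs
#'
#' Summarises (min, quartiles, median, mean, max) the BH-adjusted FDR of all
#' flagged DEGs and of the driver-DEG subset.  A lower driver-group FDR
#' indicates that network-central DEGs are the statistically safer calls.
#'
#' @param deg_table A `deg_table`.
#' @param driver_degs Character vector, must be a subset of the table's genes.
#' @return List with `summary` (data.frame, one row per group) and `values`
#'   (per-gene FDR with group label, exportable).
#' @export
fdr_comparison <- function(deg_table, driver_degs) {
  driver_degs <- unique(as.character(driver_degs))
  if (!all(driver_degs %in% deg_table$gene)) {
    stopf("driver_degs contains gene(s) absent from the DEG table")
  }
  deg_fdr <- deg_table$fdr[deg_table$is_deg]
  drv_fdr <- deg_table$fdr[deg_table$gene %in% driver_degs]
  summarise <- function(v, group) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = group, n = length(v), min = min(v), q1 = q[1],
               median = q[2], mean = mean(v), q3 = q[3], max = max(v),
               stringsAsFactors = FALSE)
  }
  pieces <- list()
  if (length(deg_fdr) > 0) pieces <- c(pieces, list(summarise(deg_fdr, "degs")))
  if (length(drv_fdr) > 0) {
    pieces <- c(pieces, list(summarise(drv_fdr, "driver_degs")))
  } else {
    warnf("empty driver-DEG set; summarising DEGs only")
  }
  summary <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(group = character(0), n = integer(0), min = numeric(0),
               q1 = numeric(0), median = numeric(0), mean = numeric(0),
               q3 = numeric(0), max = numeric(0))
  values <- rbind(
    data.frame(gene = deg_table$gene[deg_table$is_deg], fdr = deg_fdr,
               group = rep("degs", length(deg_fdr)),
               stringsAsFactors = FALSE),
    data.frame(gene = deg_table$gene[deg_table$gene %in% driver_degs],
               fdr = drv_fdr,
               group = rep("driver_degs", length(drv_fdr)),
               stringsAsFactors = FALSE)
  )
  list(summary = summary, values = values)
}

#' Driver DEGs recovered by external driver-gene catalogues
#'
#' Genes of `driver_degs` present in at least `min_tools` of the supplied
#' tool gene sets.  Monotone non-increasing in `min_tools`.
#'
#' @param driver_degs Character vector of driver-DEG symbols.
#' @param tool_gene_sets Named list of gene-symbol vectors, one per tool.
#' @param min_tools Minimum number of catalogues a gene must appear in.
#' @return Sorted character vector.
#' @export
benchmark_overlap <- function(driver_degs, tool_gene_sets, min_tools = 2) {
  if (length(tool_gene_sets) == 0) stopf("empty tool mapping")
  if (min_tools < 1) stopf("'min_tools' must be >= 1")
  driver_degs <- unique(as.character(driver_degs))
  hits <- vapply(driver_degs, function(g) {
    sum(vapply(tool_gene_sets, function(s) g %in% s, logical(1)))
  }, integer(1))
  sort(driver_degs[hits >= min_tools])
}
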