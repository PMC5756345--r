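# Driver criterion and multiplex aggregation.  A gene is a network driver in
# pathway P when its pathway-restricted degree exceeds the equal-probability
# expectation in at least `min_layers` interaction layers.

#' Evaluate the driver criterion on centrality records
#'
#' Two forms of the inequality are provided.  `"literal"` compares the
#' pathway-normalised degree against the raw expectation, `di_P / k > di_E`;
#' this is the default.  `"unnormalized"` compares like with like,
#' `di_P > di_E` (equivalently `di_P / k > di_N / m`), the form a
#' degree-proportional null would suggest.  Both use strict inequality, so
#' ties and zero-degree genes are never drivers.
#'
#' @param records data.frame of centrality records (one or more rows) with
#'   columns `di_P`, `di_E`, `k`.
#' @param mode `"literal"` or `"unnormalized"`.
#' @return Logical vector, one verdict per record.
#' @export
evaluate_criterion <- function(records, mode = c("literal", "unnormalized")) {
  mode <- match.arg(mode)
  stopifnot(all(c("di_P", "di_E", "k") %in% names(records)))
  if (mode == "literal") {
    records$di_P / records$k > records$di_E
  } else {
    records$di_P > records$di_E
  }
}

#' Attach criterion verdicts to centrality records
#'
#' @param records data.frame from [build_centrality_records()].
#' @param mode Criterion mode, see [evaluate_criterion()].
#' @return `records` with added columns `passes` and `criterion_mode`.
#' @export
driver_calls <- function(records, mode = c("literal", "unnormalized")) {
  mode <- match.arg(mode)
  records$passes <- evaluate_criterion(records, mode)
  records$criterion_mode <- mode
  records
}

#' Per-layer driver gene set
#'
#' Genes passing the criterion in at least one pathway within the named
#' layer.
#'
#' @param calls data.frame from [driver_calls()].
#' @param layer_name Layer to extract.
#' @return Sorted character vector of gene symbols.
#' @export
layer_driver_set <- function(calls, layer_name) {
  if (!layer_name %in% unique(calls$layer)) {
    stopf("unknown layer '%s'", layer_name)
  }
  sort(unique(calls$gene[calls$layer == layer_name & calls$passes]))
}

#' Multiplex driver genes (at-least-t-layers rule)
#'
#' Aggregates per-layer criterion verdicts into the multiplex driver set.
#' Under `per_gene` aggregation (default) a gene qualifies when it passes in
#' at least `min_layers` layers, in any pathway per layer; under
#' `per_pathway` some single pathway must pass in at least `min_layers`
#' layers.  `per_pathway` is the stricter reading and its driver set is
#' always a subset of the `per_gene` one.
#'
#' @param calls data.frame from [driver_calls()].
#' @param min_layers Minimum number of layers (default 2).
#' @param aggregation `"per_gene"` or `"per_pathway"`.
#' @return Object of class `multiplex_driver_result`: list with
#'   `per_layer_sets`, `driver_genes`, `min_layers`, `aggregation_mode`,
#'   `criterion_mode`.
#' @export
multiplex_drivers <- function(calls, min_layers = 2,
                              aggregation = c("per_gene", "per_pathway")) {
  aggregation <- match.arg(aggregation)
  if (min_layers < 1) stopf("'min_layers' must be >= 1")
  layers <- sort(unique(calls$layer))
  per_layer <- lapply(layers, function(l) layer_driver_set(calls, l))
  names(per_layer) <- layers

  if (min_layers > length(layers)) {
    warnf("min_layers (%d) exceeds the number of layers (%d); empty driver set",
          min_layers, length(layers))
    drivers <- character(0)
  } else if (aggregation == "per_gene") {
    hits <- unique(calls[calls$passes, c("gene", "layer")])
    if (nrow(hits) == 0) {
      drivers <- character(0)
    } else {
      cnt <- table(hits$gene)
      drivers <- sort(names(cnt)[cnt >= min_layers])
    }
  } else {
    hits <- unique(calls[calls$passes, c("gene", "pathway", "layer")])
    if (nrow(hits) == 0) {
      drivers <- character(0)
    } else {
      cnt <- table(paste(hits$gene, hits$pathway, sep = "\r"))
      keys <- names(cnt)[cnt >= min_layers]
      drivers <- sort(unique(vapply(strsplit(keys, "\r", fixed = TRUE),
                                    `[[`, character(1), 1L)))
    }
  }
  structure(list(per_layer_sets = per_layer,
                 driver_genes = drivers,
                 min_layers = as.integer(min_layers),
                 aggregation_mode = aggregation,
                 criterion_mode = unique(calls$criterion_mode)[1] %||% NA_character_),
            class = "multiplex_driver_result")
}

#' @export
print.multiplex_driver_result <- function(x, ...) {
  cat(sprintf("multiplex_driver_result: %d driver gene(s) in >=%d layer(s) [%s, %s]\n",
              length(x$driver_genes), x$min_layers, x$aggregation_mode,
              x$criterion_mode))
  for (l in names(x$per_layer_sets)) {
    cat(sprintf("  %-24s %5d gene(s)\n", l, length(x$per_layer_sets[[l]])))
  }
  invisible(x)
}

#' Venn region counts of per-layer driver sets
#'
#' Assigns every gene of the union to the exact subset of layers containing
#' it and tallies each region.  All `2^L - 1` non-empty layer combinations
#' are reported, including empty regions, so counts sum to the union size.
#'
#' @param per_layer_sets Named list of gene-symbol vectors.
#' @return data.frame with columns `signature` (layer names joined by
#'   `"&"`), `n_layers`, `count`.
#' @export
venn_region_counts <- function(per_layer_sets) {
  if (length(per_layer_sets) == 0) stopf("need at least one layer set")
  layers <- names(per_layer_sets)
  if (is.null(layers) || any(!nzchar(layers))) stopf("layer sets must be named")
  universe <- sort(unique(unlist(per_layer_sets, use.names = FALSE)))
  membership <- vapply(per_layer_sets,
                       function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  if (length(universe) == 0) {
    membership <- matrix(logical(0), ncol = length(layers))
  }
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(layers)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  sig <- apply(combos, 1, function(r) paste(layers[as.logical(r)], collapse = "&"))
  count <- apply(combos, 1, function(r) {
    if (length(universe) == 0) return(0L)
    sum(apply(membership, 1, function(mrow) all(mrow == as.logical(r))))
  })
  out <- data.frame(signature = sig,
                    n_layers = as.integer(rowSums(combos)),
                    count = as.integer(count),
                    stringsAsFactors = FALSE)
  out <- out[order(out$n_layers, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
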