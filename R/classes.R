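#' Gene set collections
#'
#' A `gene_set_collection` is a named list of pathways, each a character
#' vector of unique gene symbols.  It is the container for the pathway side
#' of the driver criterion: a pathway `P` with `k` genes contributes `k` to
#' the expected-degree null.
#'
#' @param sets Named list of character vectors (pathway id -> gene symbols).
#' @param source_name Free-text provenance label (e.g. `"kegg"`, `"synthetic"`).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source_name = "custom") {
  if (!is.list(sets) || length(sets) == 0) {
    stopf("'sets' must be a non-empty named list of character vectors")
  }
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids))) stopf("every pathway needs a non-empty id")
  if (anyDuplicated(ids)) {
    stopf("duplicate pathway id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    if (length(g) == 0 || any(!nzchar(g))) stopf("empty pathway or empty gene symbol")
    unique(g)
  })
  structure(list(sets = sets, source_name = source_name),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  k <- lengths(x$sets)
  cat(sprintf("gene_set_collection '%s': %d pathways (sizes %d-%d)\n",
              x$source_name, length(x$sets), min(k), max(k)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Undirected interaction network layer
#'
#' One layer of a multiplex network: an undirected, unweighted simple graph
#' over gene symbols.  Self-loops are dropped (with a counted warning) and
#' edges are deduplicated regardless of pair order.  The node set is the
#' union of all endpoints plus any explicitly supplied isolated nodes; its
#' size is the `m` of the expected-degree null.
#'
#' @param layer_name Identifier of the interaction type
#'   (e.g. `"physical_interaction"`, `"co_localization"`).
#' @param edges Two-column matrix or data.frame of gene-symbol endpoints.
#' @param nodes Optional extra node symbols (isolated nodes).
#' @return An object of class `network_layer` with elements `layer_name`,
#'   `edges` (canonical two-column character matrix), `nodes` (sorted).
#' @export
network_layer <- function(layer_name, edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  }
  if (ncol(edges) < 2) stopf("'edges' needs two endpoint columns")
  a <- as.character(edges[, 1]); b <- as.character(edges[, 2])
  self <- a == b
  if (any(self)) {
    warnf("dropped %d self-loop(s) in layer '%s'", sum(self), layer_name)
    a <- a[!self]; b <- b[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  em <- cbind(from = lo[keep], to = hi[keep])
  all_nodes <- sort(unique(c(em, as.character(nodes))))
  structure(list(layer_name = layer_name, edges = em, nodes = all_nodes),
            class = "network_layer")
}

#' @export
print.network_layer <- function(x, ...) {
  cat(sprintf("network_layer '%s': %d nodes, %d edges\n",
              x$layer_name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_edges <- function(layer) nrow(layer$edges)

#' Multiplex network
#'
#' A named collection of [network_layer] objects over a shared gene
#' vocabulary, one per interaction type.
#'
#' @param layers Named list of `network_layer` objects (names must match each
#'   layer's `layer_name`), or an unnamed list (names taken from the layers).
#' @return An object of class `multiplex_network`.
#' @export
multiplex_network <- function(layers) {
  if (!is.list(layers) || length(layers) == 0) stopf("need at least one layer")
  ok <- vapply(layers, inherits, logical(1), "network_layer")
  if (!all(ok)) stopf("all elements must be network_layer objects")
  nm <- names(layers) %||% vapply(layers, `[[`, character(1), "layer_name")
  if (is.null(names(layers))) names(layers) <- nm
  if (anyDuplicated(nm)) stopf("duplicate layer names")
  structure(list(layers = layers), class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("multiplex_network with %d layer(s):\n", length(x$layers)))
  for (l in x$layers) {
    cat(sprintf("  %-24s %6d nodes %8d edges\n",
                l$layer_name, length(l$nodes), nrow(l$edges)))
  }
  invisible(x)
}

#' Sample class labels
#'
#' Named factor mapping sample ids onto the two-class vocabulary
#' `{normal, tumour}`.  Labels are case-folded and the spelling "tumor" is
#' accepted; anything else is an error rather than a third class.
#'
#' @param x Character vector of labels, named by sample id.
#' @return Named factor with levels `normal`, `tumour`.
#' @export
sample_labels <- function(x) {
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) stopf("labels must be named by sample id")
  if (anyDuplicated(ids)) stopf("duplicate sample id(s) in labels")
  lab <- tolower(trimws(as.character(x)))
  lab[lab == "tumor"] <- "tumour"
  bad <- setdiff(unique(lab), c("normal", "tumour"))
  if (length(bad)) stopf("unknown class label(s): %s", paste(bad, collapse = ", "))
  structure(factor(lab, levels = c("normal", "tumour")), names = ids)
}
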