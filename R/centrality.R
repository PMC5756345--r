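# Degree-centrality core: for a gene i in interaction layer N (m nodes) and
# pathway P (k genes) the method needs three quantities,
#   di_N : degree of i in the whole layer,
#   di_P : degree of i restricted to pathway co-members,
#   di_E : expected degree under equal edge probability, di_N * k / m.

# Named list mapping each node to its (unique) neighbour vector.
adjacency_list <- function(layer) {
  stopifnot(inherits(layer, "network_layer"))
  e <- layer$edges
  if (nrow(e) == 0) {
    adj <- stats::setNames(vector("list", length(layer$nodes)), layer$nodes)
    adj[] <- list(character(0))
    return(adj)
  }
  ends <- c(e[, 1], e[, 2])
  nbrs <- c(e[, 2], e[, 1])
  adj <- split(nbrs, ends)
  missing <- setdiff(layer$nodes, names(adj))
  if (length(missing)) {
    extra <- stats::setNames(vector("list", length(missing)), missing)
    extra[] <- list(character(0))
    adj <- c(adj, extra)
  }
  adj
}

#' Degree of a gene in a network layer
#'
#' Number of distinct neighbours of `gene` in the layer; a gene absent from
#' the layer has degree 0.
#'
#' @param gene Gene symbol.
#' @param layer A [network_layer].
#' @return Non-negative integer.
#' @export
degree_in_network <- function(gene, layer) {
  stopifnot(inherits(layer, "network_layer"))
  e <- layer$edges
  sum(e[, 1] == gene) + sum(e[, 2] == gene)
}

#' Degree of a gene restricted to a pathway
#'
#' Counts the distinct neighbours of `gene` in the layer that are members of
#' the pathway (the gene itself excluded).  This is the observed
#' within-pathway connectivity compared against the expected degree.
#'
#' @param gene Gene symbol.
#' @param pathway Character vector of pathway gene symbols.
#' @param layer A [network_layer].
#' @return Non-negative integer.
#' @export
degree_in_pathway <- function(gene, pathway, layer) {
  stopifnot(inherits(layer, "network_layer"))
  pathway <- unique(as.character(pathway))
  if (length(pathway) == 0) stopf("empty pathway")
  e <- layer$edges
  nbr <- c(e[e[, 1] == gene, 2], e[e[, 2] == gene, 1])
  sum(unique(nbr) %in% setdiff(pathway, gene))
}

#' Expected degree under the equal edge-probability null
#'
#' Assuming every node pair is equally likely to be linked, a gene with
#' degree `di_N` among `m` network genes is expected to have
#' `di_E = di_N * k / m` links among the `k` genes of a pathway.
#'
#' @param di_N Observed network degree (non-negative integer).
#' @param k Pathway size (positive integer).
#' @param m Layer node count (positive integer).
#' @return `di_N * k / m` at full floating precision.
#' @export
expected_degree <- function(di_N, k, m) {
  if (any(m < 1)) stopf("'m' must be >= 1")
  if (any(k < 1)) stopf("'k' must be >= 1")
  if (any(di_N < 0)) stopf("'di_N' must be non-negative")
  di_N * k / m
}

#' Centrality records for every (pathway gene, pathway, layer) triple
#'
#' For each pathway member gene (optionally intersected with `gene_filter`)
#' and each layer, computes `di_N`, `di_P`, `di_E`, `k`, and `m`.  Genes
#' absent from a layer get all-zero degrees.  Rows are ordered by
#' (pathway, gene, layer), all lexicographic.
#'
#' @param multiplex A [multiplex_network].
#' @param pathways A [gene_set_collection].
#' @param gene_filter Optional character vector restricting the genes scored
#'   (e.g. a DEG list, to score only deregulated genes).
#' @param k_mode `"annotated"` (default) counts `k` as the number of genes
#'   annotated to the pathway; `"in_layer"` restricts `k` to pathway genes
#'   present in the layer.
#' @return data.frame with columns `gene`, `pathway`, `layer`, `di_N`,
#'   `di_P`, `di_E`, `k`, `m`.
#' @export
build_centrality_records <- function(multiplex, pathways, gene_filter = NULL,
                                     k_mode = c("annotated", "in_layer")) {
  stopifnot(inherits(multiplex, "multiplex_network"),
            inherits(pathways, "gene_set_collection"))
  k_mode <- match.arg(k_mode)
  if (length(pathways$sets) == 0) stopf("no pathways supplied")
  if (!is.null(gene_filter)) gene_filter <- unique(as.character(gene_filter))

  layer_names <- sort(names(multiplex$layers))
  adj <- lapply(multiplex$layers, adjacency_list)
  m_by_layer <- vapply(multiplex$layers, function(l) length(l$nodes), integer(1))

  out <- vector("list", length(pathways$sets) * length(layer_names))
  idx <- 0L
  for (pid in sort(names(pathways$sets))) {
    members <- sort(pathways$sets[[pid]])
    genes <- if (is.null(gene_filter)) members else intersect(members, gene_filter)
    if (length(genes) == 0) next
    for (ln in layer_names) {
      a <- adj[[ln]]
      m <- m_by_layer[[ln]]
      k <- if (k_mode == "annotated") length(members) else
        sum(members %in% multiplex$layers[[ln]]$nodes)
      di_N <- integer(length(genes))
      di_P <- integer(length(genes))
      for (j in seq_along(genes)) {
        nb <- a[[genes[j]]]
        if (is.null(nb)) next
        di_N[j] <- length(nb)
        # self-loops are dropped at ingest, so nb never contains the gene,
        # but the gene itself must still not count as a co-member target
        di_P[j] <- sum(nb %in% setdiff(members, genes[j]))
      }
      k_eff <- max(k, 1L)
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        gene = genes, pathway = pid, layer = ln,
        di_N = di_N, di_P = di_P,
        di_E = expected_degree(di_N, k_eff, m),
        k = k_eff, m = m,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- out[seq_len(idx)]
  if (idx == 0L) {
    return(data.frame(gene = character(0), pathway = character(0),
                      layer = character(0), di_N = integer(0),
                      di_P = integer(0), di_E = numeric(0),
                      k = integer(0), m = integer(0)))
  }
  rec <- do.call(rbind, out)
  rec <- rec[order(rec$pathway, rec$gene, rec$layer), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Write centrality records as TSV
#'
#' @param records data.frame from [build_centrality_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centrality_records <- function(records, path) {
  write_tsv(records, path)
}
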