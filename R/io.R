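# Readers and writers for the plain-text formats the pipeline touches:
# GMT gene sets, edge-list TSV / SIF network layers, count matrices, sample
# labels, and the result tables.  Gene symbols are case-folded to upper case
# at ingest, because symbol case is inconsistent across pathway and network
# sources.

#' Read a gene set collection from a GMT file
#'
#' One gene set per line: `id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are collapsed with a warning; duplicate
#' pathway ids are an error.
#'
#' @param path Path to a GMT file.
#' @param format Only `"gmt"` is supported.
#' @return A [gene_set_collection].
#' @export
read_gene_sets <- function(path, format = c("gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("empty GMT file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stopf("malformed GMT line %d (fewer than 3 tab-separated fields)",
          which(nf < 3)[1])
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stopf("duplicate pathway id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n_dup <- 0L
  sets <- lapply(fields, function(f) {
    g <- toupper(f[-(1:2)])
    g <- g[nzchar(g)]
    u <- unique(g)
    n_dup <<- n_dup + (length(g) - length(u))
    u
  })
  names(sets) <- ids
  if (n_dup > 0) warnf("collapsed %d duplicate gene symbol(s) within pathways", n_dup)
  gene_set_collection(sets, source_name = basename(path))
}

#' Write a gene set collection to GMT
#'
#' @param gsc A [gene_set_collection].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, gsc$source_name, gsc$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read one interaction network layer
#'
#' `edge_tsv` rows are `geneA<TAB>geneB[<TAB>weight]`; any weight column is
#' ignored since the driver criterion uses unweighted degree.  `sif` rows
#' are `A relation B [B2 ...]` and fan out to one edge per trailing node.
#' Edges are undirected and deduplicated; self-loops are dropped with a
#' counted warning.
#'
#' @param path Path to the edge file.
#' @param format `"edge_tsv"` or `"sif"`.
#' @param layer_name Name recorded on the layer (interaction type).
#' @return A [network_layer].
#' @export
read_network_layer <- function(path, format = c("edge_tsv", "sif"),
                               layer_name = "layer") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("empty network file: %s", path)
  fields <- strsplit(trimws(lines), "[\t ]+")
  if (format == "edge_tsv") {
    nf <- lengths(fields)
    if (any(nf < 2)) stopf("line %d has fewer than 2 columns", which(nf < 2)[1])
    a <- toupper(vapply(fields, `[[`, character(1), 1L))
    b <- toupper(vapply(fields, `[[`, character(1), 2L))
    edges <- cbind(a, b)
  } else {
    nf <- lengths(fields)
    if (any(nf < 3)) stopf("SIF line %d has fewer than 3 fields", which(nf < 3)[1])
    pieces <- lapply(fields, function(f) {
      src <- toupper(f[1L])
      tgt <- toupper(f[-(1:2)])
      cbind(rep(src, length(tgt)), tgt)
    })
    edges <- do.call(rbind, pieces)
  }
  network_layer(layer_name, edges)
}

#' Write a network layer as a two-column edge TSV
#'
#' @param layer A [network_layer].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_layer <- function(layer, path) {
  stopifnot(inherits(layer, "network_layer"))
  # headerless two-column TSV, the conventional edge-list layout
  writeLines(paste(layer$edges[, 1], layer$edges[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read a gene-by-sample count matrix
#'
#' TSV with a header row of sample ids; first column gene symbols.  Counts
#' must be numeric and non-negative; duplicate gene rows are an error.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows (upper-cased symbols), samples in
#'   columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("count matrix needs a gene column and >=1 sample column")
  genes <- toupper(as.character(df[[1]]))
  if (anyDuplicated(genes)) {
    stopf("duplicate gene row(s): %s",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stopf("non-numeric count cell(s) in %s", path)
  if (anyNA(mat)) stopf("missing count cell(s) in %s", path)
  if (any(mat < 0)) stopf("negative count cell(s) in %s", path)
  rownames(mat) <- genes
  if (anyDuplicated(colnames(mat))) stopf("duplicate sample id(s) in header")
  mat
}

#' Write a count matrix as TSV
#'
#' @param mat Numeric gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @param gene_col Name of the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, gene_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_col
  write_tsv(df, path)
}

#' Read sample class labels
#'
#' Two-column TSV (`sample`, `label`) with a header.  Labels are mapped
#' case-insensitively onto `{normal, tumour}`.
#'
#' @param path Path to the label file.
#' @return Named factor as returned by [sample_labels()].
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("label file needs two columns (sample, label)")
  sample_labels(structure(as.character(df[[2]]), names = as.character(df[[1]])))
}

#' Write sample labels as TSV
#'
#' @param labels Named factor/character of class labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write_tsv(data.frame(sample = names(labels), label = as.character(labels),
                       stringsAsFactors = FALSE), path)
}
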