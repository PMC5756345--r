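# In-silico validation: per-gene random-forest classification of tumour vs
# normal with stratified 10-fold cross-validation; the AUC is computed from
# the pooled out-of-fold class-probability scores and genes are ranked by it.

#' Random-forest validation settings
#'
#' @param n_trees Number of trees grown per forest (default 500).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment and tree growing.
#' @param mtry_rule Only `"sqrt_p"`: `mtry = max(1, ceiling(sqrt(p)))` where
#'   `p` is the number of predictors (1 for the per-gene models).
#' @return List of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500, n_folds = 10, seed = 1,
                      mtry_rule = c("sqrt_p")) {
  mtry_rule <- match.arg(mtry_rule)
  if (n_trees < 1) stopf("'n_trees' must be >= 1")
  if (n_folds < 2) stopf("'n_folds' must be >= 2")
  structure(list(n_trees = as.integer(n_trees), n_folds = as.integer(n_folds),
                 seed = as.integer(seed), mtry_rule = mtry_rule),
            class = "rf_config")
}

rf_mtry <- function(p) max(1L, as.integer(ceiling(sqrt(p))))

#' Stratified cross-validation folds
#'
#' Partitions the samples into `k` folds preserving the class balance to
#' within one sample per fold.  If the smaller class has fewer than `k`
#' members, `k` is reduced to that class size with a warning.
#'
#' @param labels Named factor from [sample_labels()].
#' @param k Number of folds.
#' @param seed Integer seed; identical seeds give identical folds.
#' @return List of `k` character vectors of sample ids.
#' @export
stratified_folds <- function(labels, k, seed) {
  tab <- table(labels)
  if (any(tab == 0)) stopf("both classes must be present")
  k_eff <- min(k, min(tab))
  if (k_eff < k) {
    warnf("reducing folds from %d to %d (smallest class has %d samples)",
          k, k_eff, min(tab))
  }
  with_seed(seed, {
    folds <- vector("list", k_eff)
    for (cls in levels(labels)) {
      ids <- sample(names(labels)[labels == cls])
      assign_to <- rep(seq_len(k_eff), length.out = length(ids))
      for (f in seq_len(k_eff)) {
        folds[[f]] <- c(folds[[f]], ids[assign_to == f])
      }
    }
    folds
  })
}

#' AUC from scores by the rank statistic
#'
#' Mann-Whitney form of the area under the ROC curve: average ranks of the
#' positive-class scores, so ties contribute one half.
#'
#' @param scores Numeric classifier scores (higher = more tumour-like).
#' @param truth Logical or factor; `TRUE`/`"tumour"` marks positives.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(scores, truth) {
  if (is.factor(truth)) truth <- truth == "tumour"
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated random-forest AUC for one gene
#'
#' Trains a random forest per fold on the single gene's expression values
#' (`p = 1`, so `mtry = 1`) and pools the out-of-fold tumour-class
#' probability scores; the AUC is then computed by the rank statistic.  A
#' constant gene cannot separate the classes and is reported as AUC 0.5 with
#' a warning.
#'
#' @param expr Expression matrix (genes x samples); normalized or raw scale,
#'   the forest is scale-insensitive.
#' @param labels Named factor from [sample_labels()].
#' @param gene Gene symbol, must be a row of `expr`.
#' @param config An [rf_config()].
#' @return List of class `auc_record`: `gene`, `auc`, `n_positive`,
#'   `n_negative`.
#' @export
per_gene_auc <- function(expr, labels, gene, config = rf_config()) {
  if (!gene %in% rownames(expr)) stopf("gene '%s' absent from the matrix", gene)
  labels <- labels[intersect(names(labels), colnames(expr))]
  x <- expr[gene, names(labels)]
  n1 <- sum(labels == "tumour"); n0 <- sum(labels == "normal")
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")

  rec <- function(auc) {
    structure(list(gene = gene, auc = auc, n_positive = n1, n_negative = n0),
              class = "auc_record")
  }
  if (stats::var(x) == 0) {
    warnf("gene '%s' is constant; AUC defined as 0.5", gene)
    return(rec(0.5))
  }

  gene_seed <- derive_seed(config$seed, string_offset(gene))
  folds <- stratified_folds(labels, config$n_folds, gene_seed)
  scores <- stats::setNames(numeric(length(labels)), names(labels))
  for (f in seq_along(folds)) {
    test_ids <- folds[[f]]
    train_ids <- setdiff(names(labels), test_ids)
    xtr <- data.frame(expr = x[train_ids])
    ytr <- droplevels(labels[train_ids])
    if (nlevels(ytr) < 2) stopf("a training fold lost a class; reduce folds")
    fit <- with_seed(derive_seed(gene_seed, f), {
      randomForest::randomForest(x = xtr, y = ytr,
                                 ntree = config$n_trees, mtry = rf_mtry(1L))
    })
    pr <- stats::predict(fit, newdata = data.frame(expr = x[test_ids]),
                         type = "prob")
    scores[test_ids] <- pr[, "tumour"]
  }
  rec(auc_from_scores(scores, labels))
}

#' @export
print.auc_record <- function(x, ...) {
  cat(sprintf("auc_record %s: AUC = %.3f (%d tumour / %d normal)\n",
              x$gene, x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' Per-gene AUC table for a set of genes
#'
#' @inheritParams per_gene_auc
#' @param genes Character vector of gene symbols.
#' @return data.frame with columns `gene`, `auc`, `n_positive`,
#'   `n_negative`, ordered as ranked by [rank_top_k()] over all genes.
#' @export
per_gene_auc_table <- function(expr, labels, genes, config = rf_config()) {
  genes <- unique(as.character(genes))
  recs <- lapply(genes, function(g) per_gene_auc(expr, labels, g, config))
  df <- data.frame(gene = vapply(recs, `[[`, character(1), "gene"),
                   auc = vapply(recs, `[[`, numeric(1), "auc"),
                   n_positive = vapply(recs, `[[`, integer(1), "n_positive"),
                   n_negative = vapply(recs, `[[`, integer(1), "n_negative"),
                   stringsAsFactors = FALSE)
  rank_top_k(df, k = nrow(df))
}

#' Top-k genes by AUC
#'
#' Descending AUC, ties broken by ascending gene symbol; if fewer than `k`
#' records exist, all are returned.
#'
#' @param records data.frame with columns `gene`, `auc`.
#' @param k Number of genes to keep (default 10).
#' @return data.frame slice with a `rank` column.
#' @export
rank_top_k <- function(records, k = 10) {
  if (k < 1) stopf("'k' must be >= 1")
  ord <- order(-records$auc, records$gene)
  out <- records[ord, , drop = FALSE][seq_len(min(k, nrow(records))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Mean AUC over a rank band
#'
#' Mean AUC of the genes ranked `lo` to `hi` (inclusive) under the
#' [rank_top_k()] ordering, e.g. ranks 11-50 of a condition's driver DEGs.
#'
#' @param records data.frame with columns `gene`, `auc`.
#' @param lo,hi Rank band bounds, `1 <= lo <= hi <= nrow(records)`.
#' @return Mean AUC of the band.
#' @export
rank_band_mean_auc <- function(records, lo, hi) {
  if (lo < 1 || hi < lo || hi > nrow(records)) {
    stopf("rank band [%d, %d] outside 1..%d", lo, hi, nrow(records))
  }
  ranked <- rank_top_k(records, k = nrow(records))
  mean(ranked$auc[lo:hi])
}
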