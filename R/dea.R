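# Differential expression between normal and tumour classes.  The selection
# thresholds are |log2 fold change| > 1 and Benjamini-Hochberg FDR < 0.01,
# applied to a Welch t-test on log2 counts-per-million.

#' Log2 counts-per-million normalization
#'
#' `value(g, s) = log2(1e6 * (count + 1) / (libsize_s + n_genes))`; the
#' pseudo-count of 1 per gene adds `n_genes` to each library size.
#'
#' @param mat Non-negative count matrix, genes x samples.
#' @return Real matrix of the same shape.
#' @export
normalize_counts <- function(mat) {
  if (is.null(dim(mat)) || ncol(mat) < 1) stopf("need a matrix with >= 1 sample")
  if (any(mat < 0)) stopf("negative counts")
  lib <- colSums(mat)
  if (any(lib == 0)) {
    stopf("all-zero sample(s): %s",
          paste(colnames(mat)[lib == 0], collapse = ", "))
  }
  denom <- lib + nrow(mat)
  log2(sweep(mat + 1, 2, denom, "/") * 1e6)
}

#' Per-gene Welch t-test between tumour and normal samples
#'
#' The log fold change is the tumour-minus-normal difference of class means
#' on the log2 scale; the p-value is a two-sided Welch (unequal variance)
#' t-test.  Genes with zero variance in both classes get `p = 1`.
#'
#' @param norm Normalized (log2) expression matrix, genes x samples.
#' @param labels Named factor from [sample_labels()]; samples missing from
#'   the matrix are dropped with a warning.
#' @return data.frame with columns `gene`, `log_fc`, `p_value`.
#' @export
differential_test <- function(norm, labels) {
  ids <- names(labels)
  missing <- setdiff(ids, colnames(norm))
  if (length(missing)) {
    warnf("%d labelled sample(s) absent from the matrix; ignored", length(missing))
    labels <- labels[setdiff(ids, missing)]
  }
  unlabeled <- setdiff(colnames(norm), names(labels))
  if (length(unlabeled)) {
    warnf("%d matrix sample(s) without labels; ignored", length(unlabeled))
  }
  x <- norm[, names(labels), drop = FALSE]
  is_t <- labels == "tumour"
  n1 <- sum(is_t); n0 <- sum(!is_t)
  if (n1 < 2 || n0 < 2) stopf("each class needs >= 2 samples (normal=%d, tumour=%d)", n0, n1)

  xt <- x[, is_t, drop = FALSE]
  xn <- x[, !is_t, drop = FALSE]
  m1 <- rowMeans(xt); m0 <- rowMeans(xn)
  v1 <- rowSums((xt - m1)^2) / (n1 - 1)
  v0 <- rowSums((xn - m0)^2) / (n0 - 1)
  lfc <- m1 - m0

  se2 <- v1 / n1 + v0 / n0
  p <- rep(1, nrow(x))
  ok <- se2 > 0
  tstat <- (m1[ok] - m0[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v0[ok] / n0)^2 / (n0 - 1))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)

  data.frame(gene = rownames(x), log_fc = unname(lfc), p_value = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, clipped to 1, order-preserving with the input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when `|log_fc| > logfc_thr` (strict) and its BH-adjusted
#' FDR is below `fdr_thr` (strict).
#'
#' @param test_output data.frame with columns `gene`, `log_fc`, `p_value`.
#' @param logfc_thr Log2 fold-change threshold (default 1).
#' @param fdr_thr FDR threshold (default 0.01).
#' @param condition_id Label stored on the table (e.g. a cancer type).
#' @return `deg_table`: data.frame `gene`, `log_fc`, `p_value`, `fdr`,
#'   `is_deg`, with attribute `condition_id`.
#' @export
select_degs <- function(test_output, logfc_thr = 1, fdr_thr = 0.01,
                        condition_id = "condition") {
  if (logfc_thr <= 0 || fdr_thr <= 0) stopf("thresholds must be positive")
  out <- test_output
  out$fdr <- bh_adjust(out$p_value)
  out$is_deg <- (out$log_fc > logfc_thr | out$log_fc < -logfc_thr) &
    out$fdr < fdr_thr
  attr(out, "condition_id") <- condition_id
  class(out) <- c("deg_table", class(out))
  out
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("deg_table '%s': %d genes tested, %d DEGs\n",
              attr(x, "condition_id"), nrow(x), sum(x$is_deg)))
  invisible(x)
}

#' Full differential expression analysis from raw counts
#'
#' Drops all-zero genes (with a message), normalizes to log2 CPM, runs the
#' Welch test, and flags DEGs.
#'
#' @param counts Non-negative count matrix, genes x samples.
#' @param labels Named factor from [sample_labels()].
#' @inheritParams select_degs
#' @return A `deg_table`, see [select_degs()].
#' @export
run_dea <- function(counts, labels, logfc_thr = 1, fdr_thr = 0.01,
                    condition_id = "condition") {
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    message(sprintf("dropping %d all-zero gene(s) before testing", sum(zero)))
    counts <- counts[!zero, , drop = FALSE]
  }
  norm <- normalize_counts(counts)
  tt <- differential_test(norm, labels)
  select_degs(tt, logfc_thr = logfc_thr, fdr_thr = fdr_thr,
              condition_id = condition_id)
}

#' Write a DEG table as TSV
#'
#' @param deg_table A `deg_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg_table, path) {
  df <- as.data.frame(deg_table)
  df$condition <- attr(deg_table, "condition_id")
  write_tsv(df, path)
}
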