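#' Filter a differential-expression table by fold change
#'
#' Applies the knockdown-vs-control filtering rules: transcripts on the X
#' and Y chromosomes are removed first (they confound a knockdown contrast
#' across lines of different sex and are omitted throughout the pipeline),
#' then only transcripts with more than `fold_threshold`-fold difference are
#' retained (strict inequality on |log2fc| > log2(fold_threshold); records
#' sitting exactly on the boundary are excluded and counted). Retained
#' transcripts are labelled by regulation direction: negative log2fc
#' (knockdown minus control) means the transcript went down upon knockdown,
#' i.e. is activated by the factor; positive means repressed by the factor.
#'
#' @param records Data frame with columns `transcript_id`, `chrom`,
#'   `log2fc`, `padj` (see [read_de_table()]).
#' @param fold_threshold Fold-change threshold (> 1; default 2.0, i.e. the
#'   "> 2.0-fold" rule).
#' @param drop_sex_chromosomes Remove chrX/chrY transcripts before filtering
#'   (default `TRUE`).
#' @param padj_threshold Optional adjusted-p cutoff; when set, retained
#'   records must additionally have `padj <= padj_threshold` (missing padj
#'   fails the requirement). Off by default: the fold-change rule alone
#'   defines the filtered set.
#' @return A list of class `filtered_de`: `retained` (data frame with a
#'   `direction` column, `"down_upon_kd"` or `"up_upon_kd"`), `n_down`,
#'   `n_up`, `n_boundary` (records dropped exactly on the threshold),
#'   `fold_threshold`.
#' @export
filter_de <- function(records, fold_threshold = 2,
                      drop_sex_chromosomes = TRUE, padj_threshold = NULL) {
  if (fold_threshold <= 1) stopf("fold_threshold must be > 1")
  need <- c("transcript_id", "chrom", "log2fc")
  if (!all(need %in% names(records))) {
    stopf("records must have columns %s", paste(need, collapse = ", "))
  }
  df <- as.data.frame(records)
  if (drop_sex_chromosomes) {
    df <- df[!is_sex_chromosome(df$chrom), , drop = FALSE]
  }
  thr <- log2(fold_threshold)
  n_boundary <- sum(abs(df$log2fc) == thr)
  keep <- abs(df$log2fc) > thr
  if (!is.null(padj_threshold)) {
    keep <- keep & !is.na(df$padj) & df$padj <= padj_threshold
  }
  retained <- df[keep, , drop = FALSE]
  retained$direction <- ifelse(retained$log2fc < 0, "down_upon_kd",
                               "up_upon_kd")
  rownames(retained) <- NULL
  structure(list(retained = retained,
                 n_down = sum(retained$direction == "down_upon_kd"),
                 n_up = sum(retained$direction == "up_upon_kd"),
                 n_boundary = n_boundary,
                 fold_threshold = fold_threshold),
            class = "filtered_de")
}

#' @export
print.filtered_de <- function(x, ...) {
  cat(sprintf("Filtered DE: %d transcripts beyond %.1f-fold (%d down upon knockdown, %d up); %d exactly on the boundary (dropped)\n",
              nrow(x$retained), x$fold_threshold, x$n_down, x$n_up,
              x$n_boundary))
  invisible(x)
}

#' Heatmap row order for an expression matrix
#'
#' Standardizes each transcript row to mean 0 and unit standard deviation
#' (constant rows are left at 0 rather than erroring) and clusters rows with
#' Ward linkage on euclidean distances — the classic expression-heatmap
#' configuration. Returns the dendrogram and its leaf order.
#'
#' @param matrix Numeric matrix, transcripts in rows (>= 2), samples in
#'   columns.
#' @return List with `linkage` (an [stats::hclust] object) and `order`
#'   (row indices in leaf order).
#' @export
expression_heatmap_order <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2L) stopf("need >= 2 transcripts")
  ctr <- m - rowMeans(m)
  sds <- apply(m, 1L, stats::sd)
  z <- ctr / ifelse(sds > 0, sds, 1)   # constant rows stay at 0
  hc <- hierarchical_cluster(z, method = "ward", metric = "euclidean")
  list(linkage = hc, order = hc$order)
}
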