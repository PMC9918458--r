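# Normalization and QC for the assembled multi-study expression matrix.
#
# The pipeline starts from a log2 probe x sample matrix (RMA-style output);
# these operations bring the studies onto a common distribution, flag
# anomalous samples, and provide the variance/PCA/clustering views used to
# judge whether a multi-study compendium is usable.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution given
#' by the cross-sample mean of sorted value vectors. Ties within a sample
#' receive the mean of the corresponding reference quantiles. Idempotent.
#'
#' @param m Numeric log2 matrix, probes x samples, with row/col names.
#' @return Matrix of the same shape and dimnames.
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' rownames(m) <- paste0("p", 1:3)
#' quantile_normalize(m)  # both columns become (2.5, 3.5, 4.5)
#' @export
quantile_normalize <- function(m) {
  check_expression_matrix(m)
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Select the probes with highest variance
#'
#' Returns the `k` probe ids with largest sample variance (n-1 denominator)
#' across all samples, in descending variance order; ties are broken by
#' lexicographic probe id.
#'
#' @param m Expression matrix (probes x samples).
#' @param k Number of probes to keep; must not exceed `nrow(m)`.
#' @return Character vector of `k` probe ids.
#' @export
select_top_variance <- function(m, k) {
  check_expression_matrix(m)
  if (k > nrow(m)) stop("k exceeds the number of probes")
  v <- row_vars(m)
  ord <- order(-v, rownames(m))
  rownames(m)[ord][seq_len(k)]
}

#' Principal component analysis of samples
#'
#' Samples are centered (per probe) and decomposed; components are returned
#' with a deterministic sign convention (the largest-magnitude loading of
#' each component is positive).
#'
#' @param m Expression matrix (probes x samples).
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x k), `loadings` (probes x k) and
#'   `variance_explained` (length-k fractions of total variance,
#'   non-increasing, summing to <= 1).
#' @export
pca_samples <- function(m, n_components = 2) {
  check_expression_matrix(m)
  if (ncol(m) < 2) stop("PCA needs >= 2 samples")
  if (n_components > min(dim(m))) stop("n_components exceeds matrix rank bound")
  fit <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- n_components
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  # sign convention: dominant loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(fit$sdev^2)
  list(
    scores = scores,
    loadings = loadings,
    variance_explained = fit$sdev[seq_len(k)]^2 / total_var
  )
}

#' Hierarchical clustering of samples
#'
#' Complete-linkage (default) agglomerative clustering of samples, with an
#' optional flat cut into `k` groups.
#'
#' @param m Expression matrix (probes x samples).
#' @param k Optional number of flat clusters to cut.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param metric Distance metric passed to [stats::dist()].
#' @return List with `tree` (an `hclust` object over samples) and `labels`
#'   (named integer vector, `NULL` when `k` is missing).
#' @export
hierarchical_cluster <- function(m, k = NULL, linkage = "complete", metric = "euclidean") {
  check_expression_matrix(m)
  if (ncol(m) < 2) stop("clustering needs >= 2 samples")
  ok_metric <- c("euclidean", "maximum", "manhattan", "canberra", "binary", "minkowski")
  if (!metric %in% ok_metric) stop("unknown metric: ", metric)
  d <- stats::dist(t(m), method = metric)
  tree <- stats::hclust(d, method = linkage)
  labels <- if (!is.null(k)) stats::cutree(tree, k = k) else NULL
  list(tree = tree, labels = labels)
}

#' Drop samples from a matrix and its sample sheet
#'
#' @param m Expression matrix.
#' @param sheet Sample sheet data frame (`sample_id`, `tissue`, `study_id`).
#' @param ids Sample ids to exclude; all must exist.
#' @return List with the reduced `matrix` and `sheet`; remaining sample
#'   order is preserved.
#' @export
exclude_samples <- function(m, sheet, ids) {
  check_expression_matrix(m)
  check_sample_sheet(sheet, m)
  unknown <- setdiff(ids, colnames(m))
  if (length(unknown)) stop("unknown sample ids: ", paste(unknown, collapse = ", "))
  keep <- setdiff(colnames(m), ids)
  list(
    matrix = m[, keep, drop = FALSE],
    sheet = sheet[match(keep, sheet$sample_id), , drop = FALSE]
  )
}

#' Z-score rows of a matrix
#'
#' Standardizes every row to mean 0 and sd 1 (n-1 denominator), the scaling
#' used for read-count heatmaps.
#'
#' @param m Numeric matrix with row names.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  check_expression_matrix(m)
  v <- row_vars(m)
  if (any(v == 0)) {
    stop("constant rows cannot be z-scored: ",
         paste(utils::head(rownames(m)[v == 0], 5), collapse = ", "))
  }
  (m - rowMeans(m)) / sqrt(v)
}
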