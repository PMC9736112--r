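#' Stratify samples by hierarchical clustering with a fixed tree cut
#'
#' Agglomerative clustering of the samples (columns) on Euclidean distances,
#' with missing abundances replaced by `missing_fill` *for the distance
#' computation only*, so that both abundance and the pattern of value
#' missingness shape the tree. The tree is cut at a fixed height to produce
#' sample clusters.
#'
#' @param mat Numeric matrix, proteoforms x samples; may contain `NA`.
#' @param cut_height Tree-cut height (default 1400; a cut above the root
#'   yields a single cluster with a warning, a cut at 0 gives one cluster per
#'   sample).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @param missing_fill Value substituted for `NA` in the distance computation
#'   (default 0).
#' @return Object of class `sample_clustering`: list with `clusters` (tibble
#'   `sample`, `cluster`; labels contiguous from 1), `n_clusters`, `heights`
#'   (merge heights), and the `hclust` tree. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
cluster_samples <- function(mat, cut_height = 1400, linkage = "complete",
                            missing_fill = 0) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2, cut_height >= 0)
  filled <- mat
  filled[is.na(filled)] <- missing_fill
  tree <- stats::hclust(stats::dist(t(filled), method = "euclidean"),
                        method = linkage)
  if (cut_height > max(tree$height)) {
    warning("cut height ", cut_height, " is above the tree root (",
            round(max(tree$height), 2), "); one cluster", call. = FALSE)
  }
  labels <- stats::cutree(tree, h = cut_height)
  structure(
    list(
      clusters = tibble::tibble(sample = colnames(mat),
                                cluster = as.integer(unname(labels))),
      n_clusters = max(labels),
      heights = tree$height,
      tree = tree
    ),
    class = "sample_clustering"
  )
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering> ", nrow(x$clusters), " samples in ",
      x$n_clusters, " clusters\n", sep = "")
  print(table(cluster = x$clusters$cluster))
  invisible(x)
}

#' Tree-cut height yielding a given number of clusters
#'
#' Returns the midpoint of the height interval over which cutting the tree
#' produces exactly `k` clusters — a convenience for tuning the fixed cut of
#' [cluster_samples()] to a known stratification.
#'
#' @param clustering A `sample_clustering` (or an `hclust` tree).
#' @param k Desired number of clusters.
#' @return Cut height (numeric scalar).
#' @export
cut_height_for_k <- function(clustering, k) {
  tree <- if (inherits(clustering, "sample_clustering")) clustering$tree else clustering
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$height) + 1
  stopifnot(k >= 1, k <= n)
  h <- sort(tree$height)
  upper <- if (k == 1) max(h) else h[n - k + 1]
  lower <- if (k == n) 0 else h[n - k]
  (lower + upper) / 2
}

#' Select the samples of one cluster
#'
#' @param mat Numeric matrix, proteoforms x samples.
#' @param clustering A `sample_clustering` of those samples.
#' @param cluster Cluster label to keep.
#' @return Column-subset matrix.
#' @export
select_cluster <- function(mat, clustering, cluster) {
  keep <- clustering$clusters$sample[clustering$clusters$cluster == cluster]
  if (length(keep) == 0) stop("no samples in cluster ", cluster, call. = FALSE)
  mat[, keep, drop = FALSE]
}

#' Filter lowly expressed proteoforms
#'
#' Proteome variant of [low_expression_filter()]: keeps proteoforms with at
#' least `min_units` of normalised relative expression in at least
#' `ceiling(min_fraction * n_samples)` samples; missing values count as
#' non-expressed.
#'
#' @param mat Numeric matrix, proteoforms x samples; may contain `NA`.
#' @param min_units Expression threshold (default 5).
#' @param min_fraction Fraction of samples (default 0.2).
#' @return The row-subset matrix.
#' @export
expression_filter <- function(mat, min_units = 5, min_fraction = 0.2) {
  low_expression_filter(mat, min_value = min_units, min_fraction = min_fraction)
}

#' Minimum imputation of missing abundances
#'
#' Replaces every missing cell with the global minimum observed value of the
#' matrix (the log2-scale value of the minimum measurement), under the
#' missing-not-at-random assumption that low abundance caused the
#' missingness. No observed cell is changed.
#'
#' @param mat Numeric matrix on log2 scale; may contain `NA`.
#' @return Complete matrix.
#' @export
min_impute <- function(mat) {
  if (all(is.na(mat))) stop("all values are missing", call. = FALSE)
  mat[is.na(mat)] <- min(mat, na.rm = TRUE)
  mat
}
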