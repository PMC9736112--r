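#' Minimum number of samples implied by an expression-fraction rule
#'
#' "Expressed in at least `fraction` of the samples" translates to a count of
#' `ceiling(fraction * n_samples)` samples: for 20% of 505 samples the bound
#' is 101; for 20% of 142 samples it is 29 (strictly more than 28).
#'
#' @param n_samples Number of samples.
#' @param fraction Required fraction in (0, 1].
#' @return Integer sample count.
#' @export
min_samples_required <- function(n_samples, fraction) {
  stopifnot(n_samples >= 1, fraction > 0, fraction <= 1)
  as.integer(ceiling(fraction * n_samples))
}

#' Filter lowly expressed genes
#'
#' Keeps rows with a value of at least `min_value` in at least
#' `ceiling(min_fraction * n_samples)` samples ("at least" is inclusive on
#' both the value and the count). Missing values count as below threshold.
#' Defaults correspond to the transcriptome rule of at least 2 TPM in at
#' least 20% of samples; see [expression_filter()] for the proteome variant.
#'
#' @param mat Numeric matrix, genes x samples.
#' @param min_value Expression threshold (default 2).
#' @param min_fraction Fraction of samples (default 0.2).
#' @return The row-subset matrix.
#' @export
low_expression_filter <- function(mat, min_value = 2, min_fraction = 0.2) {
  if (!is.matrix(mat) || nrow(mat) == 0 || ncol(mat) == 0) {
    stop("`mat` must be a non-empty matrix", call. = FALSE)
  }
  required <- min_samples_required(ncol(mat), min_fraction)
  n_expressed <- rowSums(mat >= min_value, na.rm = TRUE)
  mat[n_expressed >= required, , drop = FALSE]
}

#' Split an expression matrix by WGD status
#'
#' Applies the strict purity cutoff (`purity > purity_min`), then splits the
#' remaining samples into WGD+ and WGD- sub-matrices and reports whether the
#' cohort meets the network-analysis eligibility rule: at least
#' `min_wgd_samples` WGD+ samples after the purity cutoff and (when an
#' upregulated gene list is supplied) at least `min_up_genes` ploidy-
#' upregulated genes.
#'
#' @param mat Numeric matrix, genes x samples; column names are sample ids.
#' @param calls Data frame of ploidy calls (`sample`, `wgd`, `purity`).
#' @param purity_min Strict lower purity bound (default 0.5; a sample at
#'   exactly 0.5 is excluded).
#' @param min_wgd_samples Minimum WGD+ cohort size (default 50).
#' @param min_up_genes Minimum number of upregulated genes (default 100).
#' @param up_genes Optional character vector of ploidy-upregulated genes; if
#'   `NULL` the gene condition is not assessed.
#' @return List with `wgd_plus` and `wgd_minus` matrices and a one-row
#'   `eligibility` tibble (`n_wgd_plus`, `n_wgd_minus`, `n_up_genes`,
#'   `eligible`).
#' @export
stratify_by_wgd <- function(mat, calls, purity_min = 0.5,
                            min_wgd_samples = 50, min_up_genes = 100,
                            up_genes = NULL) {
  samples <- colnames(mat)
  missing <- setdiff(samples, calls$sample)
  if (length(missing) > 0) {
    stop("samples without a ploidy call: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  calls <- calls[match(samples, calls$sample), ]
  keep <- calls$purity > purity_min
  wgd_plus <- mat[, keep & calls$wgd, drop = FALSE]
  wgd_minus <- mat[, keep & !calls$wgd, drop = FALSE]
  if (ncol(wgd_minus) == 0) warning("no WGD- samples after purity cutoff", call. = FALSE)
  if (ncol(wgd_plus) == 0) warning("no WGD+ samples after purity cutoff", call. = FALSE)
  n_up <- if (is.null(up_genes)) NA_integer_ else length(unique(up_genes))
  eligible <- ncol(wgd_plus) >= min_wgd_samples &&
    (is.null(up_genes) || n_up >= min_up_genes)
  list(
    wgd_plus = wgd_plus,
    wgd_minus = wgd_minus,
    eligibility = tibble::tibble(
      n_wgd_plus = ncol(wgd_plus),
      n_wgd_minus = ncol(wgd_minus),
      n_up_genes = n_up,
      eligible = eligible
    )
  )
}

#' Pairwise Pearson correlations between genes
#'
#' @param mat Numeric complete matrix, genes x samples (impute proteome
#'   missing values first; see [min_impute()]).
#' @param genes Optional subset of row names to correlate.
#' @return Symmetric correlation matrix with unit diagonal. Correlations
#'   involving constant genes are set to 0 and the genes recorded in the
#'   `"constant_genes"` attribute.
#' @export
pairwise_pearson <- function(mat, genes = NULL) {
  if (!is.null(genes)) {
    absent <- setdiff(genes, rownames(mat))
    if (length(absent) > 0) {
      warning(length(absent), " requested gene(s) absent from the matrix",
              call. = FALSE)
    }
    mat <- mat[intersect(genes, rownames(mat)), , drop = FALSE]
  }
  if (ncol(mat) < 3) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(mat)) {
    stop("matrix contains missing values; impute before correlating",
         call. = FALSE)
  }
  constant <- apply(mat, 1, stats::sd) == 0
  corr <- suppressWarnings(stats::cor(t(mat)))
  corr[is.na(corr)] <- 0
  diag(corr) <- 1
  attr(corr, "constant_genes") <- rownames(mat)[constant]
  corr
}

#' Calibrate the hard correlation threshold against surrogate data
#'
#' For each candidate threshold, compares the number of links (gene pairs with
#' `|r|` meeting or exceeding the threshold) in `n_sets` randomly picked gene
#' sets of `set_size` genes against surrogate data obtained by independently
#' permuting each gene's values across samples (`n_shuffles` per set). The
#' permutation destroys inter-gene correlation while preserving each gene's
#' marginal distribution exactly. A one-sided unpaired Wilcoxon rank-sum test
#' (real > surrogate) is run per threshold on the pooled counts; the chosen
#' threshold is the smallest candidate with `p < alpha`, or none.
#'
#' @param mat Numeric complete matrix, genes x samples.
#' @param thresholds Strictly increasing candidates in (0, 1)
#'   (default `c(0.6, 0.7, 0.8, 0.9)`).
#' @param n_sets Number of random gene sets (default 50).
#' @param set_size Genes per set (default 300; lowered to the row count with a
#'   warning when the matrix is smaller).
#' @param n_shuffles Surrogate datasets per set (default 50).
#' @param alpha Significance level for the rank-sum test (default 0.001).
#' @param seed Optional integer seed (governs set sampling and shuffles).
#' @return Object of class `gg_calibration`: a list with `summary` (tibble of
#'   threshold, median real/surrogate counts, p-value, pass), the
#'   `chosen_threshold` (`NA` if no candidate passes), raw count matrices, and
#'   the configuration. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
calibrate_threshold <- function(mat, thresholds = c(0.6, 0.7, 0.8, 0.9),
                                n_sets = 50, set_size = 300, n_shuffles = 50,
                                alpha = 0.001, seed = NULL) {
  stopifnot(is.matrix(mat), ncol(mat) >= 3,
            all(diff(thresholds) > 0), all(thresholds > 0 & thresholds < 1),
            n_sets >= 1, n_shuffles >= 1, alpha > 0, alpha < 1)
  if (anyNA(mat)) {
    stop("matrix contains missing values; impute before calibrating",
         call. = FALSE)
  }
  if (all(apply(mat, 1, stats::sd) == 0)) {
    warning("degenerate matrix (all rows constant): no threshold chosen",
            call. = FALSE)
    return(new_gg_calibration(thresholds, NULL, NULL, NA_real_,
                              list(n_sets = n_sets, set_size = set_size,
                                   n_shuffles = n_shuffles, alpha = alpha,
                                   seed = seed)))
  }
  if (nrow(mat) < set_size) {
    warning("matrix has ", nrow(mat), " rows < set_size ", set_size,
            "; using all rows per set", call. = FALSE)
    set_size <- nrow(mat)
  }
  if (!is.null(seed)) set.seed(seed)

  real <- matrix(0L, n_sets, length(thresholds))
  surr <- matrix(0L, n_sets * n_shuffles, length(thresholds))
  for (i in seq_len(n_sets)) {
    idx <- sample.int(nrow(mat), set_size)
    sub <- mat[idx, , drop = FALSE]
    real[i, ] <- link_counts_cpp(sub, thresholds)
    rows <- (i - 1L) * n_shuffles + seq_len(n_shuffles)
    surr[rows, ] <- surrogate_link_counts_cpp(sub, n_shuffles, thresholds)
  }

  p <- vapply(seq_along(thresholds), function(t) {
    rank_sum_greater(real[, t], surr[, t])
  }, numeric(1))
  chosen <- thresholds[which(p < alpha)[1]]
  if (length(chosen) == 0 || is.na(chosen)) chosen <- NA_real_

  new_gg_calibration(thresholds, real, surr, chosen,
                     list(n_sets = n_sets, set_size = set_size,
                          n_shuffles = n_shuffles, alpha = alpha, seed = seed),
                     p)
}

# One-sided Mann-Whitney (x > y), normal approximation with tie correction;
# degenerate all-tied input returns 1.
rank_sum_greater <- function(x, y) {
  if (length(unique(c(x, y))) == 1) return(1)
  stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
}

new_gg_calibration <- function(thresholds, real, surr, chosen, config,
                               p = rep(NA_real_, length(thresholds))) {
  summary <- tibble::tibble(
    threshold = thresholds,
    median_real = if (is.null(real)) NA_real_ else apply(real, 2, stats::median),
    median_surrogate = if (is.null(surr)) NA_real_ else apply(surr, 2, stats::median),
    p_value = p,
    pass = !is.na(p) & p < config$alpha
  )
  structure(
    list(summary = summary, chosen_threshold = chosen,
         real_counts = real, surrogate_counts = surr, config = config),
    class = "gg_calibration"
  )
}

#' @export
print.gg_calibration <- function(x, ...) {
  cat("<gg_calibration> ", x$config$n_sets, " sets x ", x$config$set_size,
      " genes, ", x$config$n_shuffles, " shuffles/set\n", sep = "")
  print(x$summary)
  if (is.na(x$chosen_threshold)) {
    cat("no threshold separates real from surrogate data at alpha =",
        x$config$alpha, "\n")
  } else {
    cat("chosen threshold:", x$chosen_threshold, "\n")
  }
  invisible(x)
}

#' Build a binary-adjacency coexpression graph
#'
#' The network is unsigned: an edge is drawn wherever `|r| >= threshold`
#' (inclusive), so strong negative correlations count as edges too. The
#' signed correlation is retained as the `r` edge attribute. Isolated nodes
#' are kept.
#'
#' @param corr Symmetric correlation matrix with row/column names.
#' @param threshold Hard threshold in (0, 1].
#' @return An undirected simple igraph graph with graph attribute `threshold`.
#' @export
build_graph <- function(corr, threshold) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            threshold > 0, threshold <= 1)
  if (is.null(rownames(corr))) {
    rownames(corr) <- colnames(corr) <- paste0("g", seq_len(nrow(corr)))
  }
  adj <- abs(corr) >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    igraph::E(g)$r <- corr[cbind(el[, 1], el[, 2])]
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}
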