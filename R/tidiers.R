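#' Tidy a threshold calibration
#'
#' One row per (candidate threshold, dataset kind, set) link count.
#'
#' @param x A `gg_calibration`.
#' @param ... Unused.
#' @return Tibble with `threshold`, `kind` (`"real"`/`"surrogate"`), `links`.
#' @export
tidy.gg_calibration <- function(x, ...) {
  if (is.null(x$real_counts)) {
    return(tibble::tibble(threshold = numeric(), kind = character(),
                          links = integer()))
  }
  thr <- x$summary$threshold
  real <- tibble::tibble(
    threshold = rep(thr, each = nrow(x$real_counts)),
    kind = "real",
    links = as.integer(x$real_counts)
  )
  surr <- tibble::tibble(
    threshold = rep(thr, each = nrow(x$surrogate_counts)),
    kind = "surrogate",
    links = as.integer(x$surrogate_counts)
  )
  dplyr::bind_rows(real, surr)
}

#' Glance at a threshold calibration
#'
#' @param x A `gg_calibration`.
#' @param ... Unused.
#' @return One-row tibble: `chosen_threshold`, `n_candidates`, `n_sets`,
#'   `set_size`, `n_shuffles`, `alpha`.
#' @export
glance.gg_calibration <- function(x, ...) {
  tibble::tibble(
    chosen_threshold = x$chosen_threshold,
    n_candidates = nrow(x$summary),
    n_sets = x$config$n_sets,
    set_size = x$config$set_size,
    n_shuffles = x$config$n_shuffles,
    alpha = x$config$alpha
  )
}

#' Tidy an MCL clustering
#'
#' @param x An `mcl_clustering`.
#' @param ... Unused.
#' @return Tibble (`node`, `cluster`).
#' @export
tidy.mcl_clustering <- function(x, ...) x$membership

#' Glance at an MCL clustering
#'
#' @param x An `mcl_clustering`.
#' @param ... Unused.
#' @return One-row tibble: `n_clusters`, `n_nodes`, `largest_cluster`,
#'   `converged`, `n_iterations`.
#' @export
glance.mcl_clustering <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$n_clusters,
    n_nodes = nrow(x$membership),
    largest_cluster = max(tabulate(x$membership$cluster)),
    converged = x$converged,
    n_iterations = x$n_iterations
  )
}

#' Tidy a sample clustering
#'
#' @param x A `sample_clustering`.
#' @param ... Unused.
#' @return Tibble (`sample`, `cluster`).
#' @export
tidy.sample_clustering <- function(x, ...) x$clusters

#' Glance at a sample clustering
#'
#' @param x A `sample_clustering`.
#' @param ... Unused.
#' @return One-row tibble: `n_clusters`, `n_samples`, `largest_cluster`,
#'   `tree_height`.
#' @export
glance.sample_clustering <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$n_clusters,
    n_samples = nrow(x$clusters),
    largest_cluster = max(tabulate(x$clusters$cluster)),
    tree_height = max(x$heights)
  )
}
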