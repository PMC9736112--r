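#' Exact right-sided hypergeometric tail
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` containing `K` members of the term.
#'
#' @param k Observed overlap.
#' @param K Term size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The tail probability.
#' @export
#' @examples
#' hypergeom_tail(3, 5, 5, 20) # 1126/15504
hypergeom_tail <- function(k, K, n, N) {
  if (!(k >= 0 && K >= 0 && n >= 0 && N >= 0 && k <= min(K, n) &&
        K <= N && n <= N)) {
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Holm (Bonferroni step-down) adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by `m - i + 1`,
#' enforces monotonicity with a running maximum, caps at 1, and maps the
#' adjusted values back to the input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, input order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "holm")
}

#' Annotation-module over-representation analysis
#'
#' Right-sided hypergeometric test of each annotation term (GO/KEGG-style,
#' typically read from GMT with [read_gmt()]) in a query gene set against an
#' explicit background universe, with Holm step-down correction across all
#' tested terms. Term memberships and the query are intersected with the
#' universe first; query genes outside the universe are dropped with a
#' warning. The universe is always explicit — for transcriptome work use all
#' genes in the DE table, for proteome work all identified proteins.
#'
#' @param query Character vector of gene symbols.
#' @param annotations Tibble (`term_id`, `term_name`, `genes` list-column) or
#'   a named list of character vectors.
#' @param universe Character vector: the background gene set.
#' @param alpha Significance level (default 0.05).
#' @return Tibble of class `gg_enrichment`, one row per term with `K >= 1`
#'   after intersection: `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_raw`,
#'   `p_holm`, `significant`, and `low_power` (`K < 3`), sorted by `p_holm`.
#' @export
enrich_modules <- function(query, annotations, universe, alpha = 0.05) {
  universe <- unique(normalise_symbols(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  annotations <- as_annotation_sets(annotations)
  query <- unique(normalise_symbols(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  n_query <- length(query)
  n_universe <- length(universe)

  res <- annotations |>
    dplyr::mutate(
      members = purrr::map(.data$genes, intersect, universe),
      K = lengths(.data$members),
      k = purrr::map_int(.data$members, ~ length(intersect(.x, query)))
    ) |>
    dplyr::filter(.data$K >= 1) |>
    dplyr::mutate(
      n = n_query, N = n_universe,
      p_raw = purrr::map2_dbl(.data$k, .data$K,
                              ~ hypergeom_tail(.x, .y, n_query, n_universe))
    )
  res$p_holm <- holm_adjust(res$p_raw)
  res <- res |>
    dplyr::mutate(
      significant = .data$p_holm < alpha,
      low_power = .data$K < 3
    ) |>
    dplyr::select("term_id", "term_name", "k", "K", "n", "N",
                  "p_raw", "p_holm", "significant", "low_power") |>
    dplyr::arrange(.data$p_holm, .data$p_raw, .data$term_id)
  class(res) <- c("gg_enrichment", class(res))
  res
}

as_annotation_sets <- function(annotations) {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("term_id", "genes") %in% names(annotations)))
    out <- tibble::as_tibble(annotations)
    if (!"term_name" %in% names(out)) out$term_name <- out$term_id
  } else if (is.list(annotations)) {
    if (is.null(names(annotations))) {
      stop("annotation list must be named by term", call. = FALSE)
    }
    out <- tibble::tibble(
      term_id = names(annotations),
      term_name = names(annotations),
      genes = unname(annotations)
    )
  } else {
    stop("`annotations` must be a data frame or named list", call. = FALSE)
  }
  out$genes <- lapply(out$genes, function(g) unique(normalise_symbols(g)))
  if (any(lengths(out$genes) == 0)) {
    stop("annotation term(s) with no members", call. = FALSE)
  }
  out
}
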