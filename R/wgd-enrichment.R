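#' Filter a differential-expression table at fixed thresholds
#'
#' Splits a DE table into ploidy-upregulated and downregulated genes using
#' strict inequalities: up means `pAdj < padj_max` and `logFC > abs_logfc_min`,
#' down means `pAdj < padj_max` and `logFC < -abs_logfc_min`. Positive logFC
#' means higher expression in WGD+ samples. Boundary values are excluded on
#' both axes. Duplicated symbols keep the row with the smallest `pAdj`.
#'
#' @param de Data frame with columns `gene`, `logFC`, `pAdj`.
#' @param padj_max Adjusted-p cutoff (default 0.05).
#' @param abs_logfc_min Absolute log2 fold-change cutoff (default 0.5).
#' @return Tibble of the significant rows with an added `direction` column
#'   (`"up"` or `"down"`). The number of duplicate rows dropped is recorded in
#'   the `"n_duplicates_dropped"` attribute.
#' @export
#' @examples
#' de <- tibble::tibble(gene = c("A", "B", "C"),
#'                      logFC = c(0.6, -1, 0.2), pAdj = c(0.01, 0.02, 0.5))
#' filter_de(de)
filter_de <- function(de, padj_max = 0.05, abs_logfc_min = 0.5) {
  stopifnot(all(c("gene", "logFC", "pAdj") %in% names(de)),
            padj_max > 0, padj_max < 1, abs_logfc_min >= 0)
  if (any(de$pAdj < 0 | de$pAdj > 1, na.rm = TRUE)) {
    stop("pAdj values outside [0, 1]", call. = FALSE)
  }
  de <- tibble::as_tibble(de)
  n0 <- nrow(de)
  de <- de |>
    dplyr::arrange(.data$pAdj) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  n_dup <- n0 - nrow(de)
  if (n_dup > 0) {
    message(n_dup, " duplicated gene row(s) dropped (kept smallest pAdj)")
  }
  out <- de |>
    dplyr::filter(.data$pAdj < padj_max, abs(.data$logFC) > abs_logfc_min) |>
    dplyr::mutate(direction = ifelse(.data$logFC > 0, "up", "down")) |>
    dplyr::arrange(dplyr::desc(.data$direction), .data$pAdj)
  attr(out, "n_duplicates_dropped") <- n_dup
  out
}

#' Exact binomial tail probability
#'
#' Right tail is `P(X >= k)` and left tail is `P(X <= k)` for
#' `X ~ Binomial(n, p0)`, computed exactly (no normal approximation).
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials.
#' @param p0 Success probability under the null.
#' @param tail `"right"` or `"left"`.
#' @return The tail probability.
#' @export
#' @examples
#' binomial_tail(7, 10, 0.5, "right") # 176/1024
binomial_tail <- function(k, n, p0, tail = c("right", "left")) {
  tail <- match.arg(tail)
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  if (n == 0) {
    warning("n = 0: tail probability is 1", call. = FALSE)
    return(1)
  }
  if (tail == "right") {
    stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  } else {
    stats::pbinom(k, n, p0, lower.tail = TRUE)
  }
}

#' Test GG enrichment among ploidy-regulated genes
#'
#' Tests whether gametogenesis-related (GG) genes are over-represented among
#' ploidy-upregulated genes (right-tailed binomial test), under-represented
#' among downregulated genes (left-tailed), and whether differentially
#' expressed GG genes trend towards upregulation rather than downregulation.
#' The background GG proportion `p0` is taken over the universe of genes
#' actually tested (the DE table), not the whole genome. The trend test
#' compares the GG-up count among GG-DE genes to the whole-transcriptome
#' up-fraction `q0 = n_up / (n_up + n_down)`.
#'
#' @param up,down Character vectors of up-/downregulated gene symbols
#'   (subsets of `universe`).
#' @param universe Character vector: all genes tested for this cohort.
#' @param catalog GG catalogue (see [filter_by_catalog()] for accepted forms).
#' @param alpha Significance level for the boolean calls (default 0.05).
#' @param tumour_type Optional cohort label carried into the result.
#' @return One-row tibble of class `gg_enrichment_call`: counts (`n_up`,
#'   `n_down`, `k_up_gg`, `k_down_gg`), `p0`, the three p-values (`p_right`,
#'   `p_left`, `p_trend`) and boolean calls (`enriched_up`, `depleted_down`,
#'   `trend_up`).
#' @export
call_enrichment <- function(up, down, universe, catalog, alpha = 0.05,
                            tumour_type = NA_character_) {
  universe <- unique(normalise_symbols(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  up <- unique(normalise_symbols(up))
  down <- unique(normalise_symbols(down))
  if (!all(up %in% universe) || !all(down %in% universe)) {
    stop("`up` and `down` must be subsets of `universe`", call. = FALSE)
  }
  gg <- intersect(catalog_symbols(catalog), universe)
  p0 <- length(gg) / length(universe)
  n_up <- length(up); n_down <- length(down)
  k_up <- sum(up %in% gg); k_down <- sum(down %in% gg)

  p_right <- if (n_up == 0) 1 else binomial_tail(k_up, n_up, p0, "right")
  p_left <- if (n_down == 0) 1 else binomial_tail(k_down, n_down, p0, "left")
  n_gg_de <- k_up + k_down
  q0 <- if (n_up + n_down > 0) n_up / (n_up + n_down) else NA_real_
  p_trend <- if (n_gg_de == 0 || is.na(q0)) {
    1
  } else {
    binomial_tail(k_up, n_gg_de, q0, "right")
  }

  out <- tibble::tibble(
    tumour_type = tumour_type,
    n_up = n_up, n_down = n_down,
    k_up_gg = k_up, k_down_gg = k_down,
    p0 = p0,
    p_right = p_right, p_left = p_left, p_trend = p_trend,
    enriched_up = n_up > 0 && p_right < alpha,
    depleted_down = n_down > 0 && p_left < alpha,
    trend_up = p_trend < alpha
  )
  class(out) <- c("gg_enrichment_call", class(out))
  out
}

#' Summarise per-cohort enrichment calls
#'
#' Binds enrichment calls into a per-tumour-type summary with GG prevalence
#' percentages, shaped like the study-wide prevalence table.
#'
#' @param calls A list of [call_enrichment()] results, or a tibble of bound
#'   rows.
#' @return Tibble with one row per tumour type.
#' @export
summarise_cohorts <- function(calls) {
  if (is.data.frame(calls)) calls <- list(calls)
  tab <- dplyr::bind_rows(calls)
  if (nrow(tab) == 0) stop("no enrichment calls supplied", call. = FALSE)
  if (anyDuplicated(tab$tumour_type)) {
    stop("duplicate tumour types: ",
         paste(unique(tab$tumour_type[duplicated(tab$tumour_type)]),
               collapse = ", "),
         call. = FALSE)
  }
  tab |>
    dplyr::mutate(
      pct_gg_up = ifelse(.data$n_up > 0, 100 * .data$k_up_gg / .data$n_up, NA_real_),
      pct_gg_down = ifelse(.data$n_down > 0, 100 * .data$k_down_gg / .data$n_down, NA_real_)
    ) |>
    dplyr::select("tumour_type", "n_up", "enriched_up", "n_down",
                  "depleted_down", "trend_up", "pct_gg_up", "pct_gg_down") |>
    dplyr::arrange(.data$tumour_type)
}
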