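#' Plot a phylostratigraphic profile
#'
#' Line plot of the per-stratum proportions, optionally against a reference
#' profile.
#'
#' @param object A [phylo_profile()].
#' @param reference Optional second `phylo_profile` drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phylo_profile <- function(object, reference = NULL, ...) {
  df <- tibble::tibble(stratum = object$stratum,
                       proportion = object$proportion,
                       set = "gene set")
  if (!is.null(reference)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      stratum = reference$stratum,
      proportion = reference$proportion,
      set = "reference"
    ))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$proportion,
                                   linetype = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = object$stratum) +
    ggplot2::labs(x = "phylostratum (1 = oldest)",
                  y = "proportion of annotated genes",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a threshold calibration
#'
#' Boxplots of real vs surrogate link counts per candidate threshold, on a
#' log scale; the chosen threshold is marked.
#'
#' @param object A `gg_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gg_calibration <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$threshold),
                                        y = .data$links + 1,
                                        fill = .data$kind)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "candidate threshold", y = "links + 1", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$chosen_threshold)) {
    p <- p + ggplot2::geom_vline(
      xintercept = match(object$chosen_threshold, sort(unique(df$threshold))),
      linetype = "dotted")
  }
  p
}

#' Plot annotation-module enrichment results
#'
#' Horizontal bars of `-log10` Holm-adjusted p-values for the top terms.
#'
#' @param object A `gg_enrichment`.
#' @param n_terms Number of top terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gg_enrichment <- function(object, n_terms = 15, ...) {
  df <- utils::head(object, n_terms)
  df$term_name <- factor(df$term_name, levels = rev(df$term_name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_holm),
                                   y = .data$term_name,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "Holm-adjusted p"), y = NULL,
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' Plot the degree distribution of a network
#'
#' @param g An igraph graph.
#' @return A ggplot object (ranked degree plot).
#' @export
plot_degree_ranking <- function(g) {
  df <- degree_ranking(g)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$degree)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "node rank", y = "degree") +
    ggplot2::theme_minimal()
}
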